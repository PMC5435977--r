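#' Validate a block structure
#'
#' A block structure partitions the columns `1..p` of a predictor matrix into
#' `M` disjoint, covering, nonempty modalities (e.g. clinical variables,
#' gene expression, copy number). Blocks are given as a list of integer
#' index vectors.
#'
#' @param blocks list of integer vectors of column indices (1-based).
#' @param p total number of columns the blocks must cover.
#' @return The validated block list, with indices stored as sorted integers.
#' @examples
#' check_blocks(list(clinical = 1:2, expr = 3:10), p = 10)
#' @export
check_blocks <- function(blocks, p) {
  if (!is.list(blocks) || length(blocks) < 1L)
    stop("'blocks' must be a nonempty list of column index vectors")
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  sizes <- vapply(blocks, length, 1L)
  if (any(sizes == 0L)) stop("every block must be nonempty")
  all_idx <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    dup <- unique(all_idx[duplicated(all_idx)])
    stop("blocks overlap: column(s) ", paste(dup, collapse = ", "),
         " appear in more than one block")
  }
  if (length(all_idx) != p || !setequal(all_idx, seq_len(p))) {
    missing <- setdiff(seq_len(p), all_idx)
    extra <- setdiff(all_idx, seq_len(p))
    if (length(missing))
      stop("blocks do not cover column(s) ", paste(missing, collapse = ", "))
    stop("block indices out of range: ", paste(extra, collapse = ", "))
  }
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  blocks
}

#' Canonicalize a penalty-factor vector
#'
#' Penalty factors are defined per modality as the ratio of that modality's
#' L1 penalty to the reference (first) modality's penalty. The fitted model
#' is invariant to multiplying the whole vector by a positive scalar, so the
#' canonical form divides by the first entry, making it 1.
#'
#' @param pf numeric vector of positive penalty factors, one per block.
#' @param M expected number of blocks (optional check).
#' @return Numeric vector with first entry exactly 1.
#' @examples
#' canonical_pf(c(2, 8))   # -> c(1, 4)
#' @export
canonical_pf <- function(pf, M = NULL) {
  pf <- as.numeric(pf)
  if (!is.null(M) && length(pf) != M)
    stop("penalty factor vector has length ", length(pf),
         " but there are ", M, " blocks")
  if (any(!is.finite(pf)) || any(pf <= 0))
    stop("all penalty factors must be positive and finite")
  pf / pf[1L]
}

# expand per-block penalty factors into a per-feature weight vector
pf_weights <- function(blocks, pf, p) {
  w <- numeric(p)
  for (m in seq_along(blocks)) w[blocks[[m]]] <- pf[m]
  w
}

#' Candidate penalty-factor vectors on a powers-of-two grid
#'
#' The default candidate set used in bi-modal benchmarks: vectors
#' `(1, 2^k)` for `k` in `kmin..kmax` (7 candidates for the default
#' `-3..3`).
#'
#' @param kmin,kmax integer exponent range.
#' @return List of length-2 penalty-factor vectors.
#' @examples
#' pf_candidates_pow2()       # (1,1/8) ... (1,8)
#' @export
pf_candidates_pow2 <- function(kmin = -3L, kmax = 3L) {
  lapply(seq(kmin, kmax), function(k) c(1, 2^k))
}
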