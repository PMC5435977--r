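# Readers and writers: delimited predictor matrices, block-structure
# configuration files, and a versioned on-disk fit format (JSON).

.fit_format_version <- 1L

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a block-structure configuration file
#'
#' Plain-text format, one block per line: `name=spec`, where `spec` is a
#' comma-separated list of 1-based inclusive column ranges (`a-b`) and/or
#' single indices, referring to predictor columns. Lines starting with `#`
#' and blank lines are ignored.
#'
#' @param path configuration file.
#' @param p number of predictor columns the blocks must cover.
#' @return Named list of integer index vectors (validated partition).
#' @export
read_blocks <- function(path, p) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no block definitions in ", path)
  blocks <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed block line: ", ln)
    name <- trimws(kv[1L])
    parts <- strsplit(trimws(kv[2L]), ",", fixed = TRUE)[[1L]]
    idx <- unlist(lapply(trimws(parts), function(tok) {
      if (grepl("^\\d+-\\d+$", tok)) {
        ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]])
        seq(ab[1L], ab[2L])
      } else if (grepl("^\\d+$", tok)) {
        as.integer(tok)
      } else stop("malformed index token '", tok, "' in block ", name)
    }))
    blocks[[name]] <- idx
  }
  check_blocks(blocks, p)
}

#' Load a delimited dataset with outcome and block structure
#'
#' Reads a samples-by-features table (CSV or TSV by file extension, header
#' row of feature names, optional non-numeric first ID column), splits off
#' the outcome column(s), and validates the block structure against the
#' remaining predictor columns.
#'
#' @param path data file.
#' @param family model family.
#' @param outcome outcome column name(s): one column for
#'   gaussian/binomial, `c(time, status)` for cox.
#' @param blocks a block list, a block-config file path, or `NULL` for a
#'   single block.
#' @return List with `x` (numeric matrix), `y` (vector or `(time, status)`
#'   matrix), `blocks`, and `ids` (row identifiers or `NULL`).
#' @export
read_dataset <- function(path, family = c("gaussian", "binomial", "cox"),
                         outcome, blocks = NULL) {
  family <- match.arg(family)
  if (length(outcome) != (if (family == "cox") 2L else 1L))
    stop("family '", family, "' needs ",
         if (family == "cox") "time and status outcome columns"
         else "exactly one outcome column")
  d <- read.table(path, header = TRUE, sep = guess_sep(path),
                  check.names = FALSE, stringsAsFactors = FALSE)
  ids <- NULL
  if (ncol(d) > 0L && !is.numeric(d[[1L]]) &&
      !(names(d)[1L] %in% outcome)) {
    ids <- as.character(d[[1L]])
    d <- d[, -1L, drop = FALSE]
  }
  missing_out <- setdiff(outcome, names(d))
  if (length(missing_out))
    stop("outcome column(s) not found: ", paste(missing_out, collapse = ", "))
  ycols <- d[outcome]
  xd <- d[setdiff(names(d), outcome)]
  notnum <- names(xd)[!vapply(xd, is.numeric, TRUE)]
  if (length(notnum))
    stop("non-numeric predictor column(s): ",
         paste(notnum, collapse = ", "))
  x <- as.matrix(xd)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("missing values in predictors, e.g. row ", bad[1L, 1L],
         ", column '", colnames(x)[bad[1L, 2L]], "' (", nrow(bad),
         " in total)")
  }
  y <- if (family == "cox") {
    ym <- as.matrix(ycols)
    if (!all(ym[, 2L] %in% c(0, 1)))
      stop("status column '", outcome[2L], "' must be 0/1")
    colnames(ym) <- c("time", "status")
    ym
  } else ycols[[1L]]
  if (is.character(blocks)) blocks <- read_blocks(blocks, ncol(x))
  else if (is.null(blocks)) blocks <- list(all = seq_len(ncol(x)))
  else blocks <- check_blocks(blocks, ncol(x))
  list(x = x, y = y, blocks = blocks, ids = ids, family = family)
}

#' Save a fitted path object to disk
#'
#' Writes a versioned JSON representation preserving coefficients at full
#' precision and all metadata needed for prediction (family, grid, penalty
#' factors, blocks, standardization constants, and for Cox fits the
#' training outcome and linear predictors for the baseline hazard).
#'
#' @param fit an `"ipflasso"` (or `"sgl"`) fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ipflasso"))
  obj <- list(
    format_version = .fit_format_version,
    package_version = as.character(packageVersion("ipfreg")),
    classes = class(fit),
    family = fit$family,
    lambda = fit$lambda,
    beta = list(values = as.vector(fit$beta), nrow = nrow(fit$beta),
                ncol = ncol(fit$beta)),
    a0 = fit$a0,
    df = unname(fit$df),
    penalty.factors = fit$penalty.factors,
    alpha = fit$alpha,
    blocks = lapply(fit$blocks, as.integer),
    feature.names = fit$feature.names,
    nobs = fit$nobs,
    center = unname(fit$center),
    scale = unname(fit$scale),
    zero.variance = as.integer(fit$zero.variance),
    cox = if (!is.null(fit$cox)) list(
      time = fit$cox$time, status = fit$cox$status,
      linpred = list(values = as.vector(fit$cox$linpred),
                     nrow = nrow(fit$cox$linpred),
                     ncol = ncol(fit$cox$linpred))) else NULL)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Load a fitted path object
#'
#' @param path file written by [write_fit()]. A format-version mismatch is
#'   an explicit error.
#' @return The reconstructed fit object.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != .fit_format_version)
    stop("fit file format version ", obj$format_version,
         " does not match supported version ", .fit_format_version)
  beta <- matrix(as.numeric(obj$beta$values), obj$beta$nrow, obj$beta$ncol)
  rownames(beta) <- obj$feature.names
  blocks <- lapply(obj$blocks, as.integer)
  fit <- list(call = NULL, family = obj$family,
              lambda = as.numeric(obj$lambda),
              beta = beta,
              a0 = if (!is.null(obj$a0)) as.numeric(obj$a0),
              df = colSums(beta != 0),
              df.block = do.call(rbind, lapply(blocks, function(b)
                colSums(beta[b, , drop = FALSE] != 0))),
              penalty.factors = as.numeric(obj$penalty.factors),
              alpha = obj$alpha,
              blocks = blocks, feature.names = obj$feature.names,
              nobs = obj$nobs, center = as.numeric(obj$center),
              scale = as.numeric(obj$scale),
              zero.variance = as.integer(obj$zero.variance))
  if (!is.null(obj$cox) && length(obj$cox))
    fit$cox <- list(time = as.numeric(obj$cox$time),
                    status = as.integer(obj$cox$status),
                    linpred = matrix(as.numeric(obj$cox$linpred$values),
                                     obj$cox$linpred$nrow,
                                     obj$cox$linpred$ncol))
  class(fit) <- obj$classes
  fit
}

#' Write a coefficient table for a chosen lambda
#'
#' TSV of `(feature, block, coefficient)` at one grid point.
#'
#' @param fit a fitted path object.
#' @param path output TSV.
#' @param index lambda grid index (default: last).
#' @export
write_coef_table <- function(fit, path, index = length(fit$lambda)) {
  blk <- character(nrow(fit$beta))
  for (m in seq_along(fit$blocks))
    blk[fit$blocks[[m]]] <- names(fit$blocks)[m]
  d <- data.frame(feature = fit$feature.names, block = blk,
                  coefficient = fit$beta[, index])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
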