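#' Areal dataset container
#'
#' One row per small area: continuous response (typically the log
#' standardised incidence ratio), design matrix with leading intercept
#' column, optional per-area sampling variances, and the neighbourhood
#' structure.
#'
#' @param y response vector.
#' @param X design matrix, n x (p+1); a leading column of ones is added if
#'   absent.
#' @param adjacency an \code{"adjacency"} object (or input accepted by
#'   \code{\link{build_adjacency}}).
#' @param sigma2 optional per-area sampling variances (all > 0).
#' @param ids optional unique area identifiers.
#' @return An object of class \code{"area_dataset"}.
#' @export
area_dataset <- function(y, X, adjacency = NULL, sigma2 = NULL, ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (!all(abs(X[, 1] - 1) < 1e-12)) X <- cbind(1, X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (ncol(X) > 1L) paste0("x", seq_len(ncol(X) - 1L)))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X are not allowed")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("area ids must be unique")
  if (!is.null(sigma2)) {
    if (length(sigma2) == 1L) sigma2 <- rep(as.numeric(sigma2), n)
    if (length(sigma2) != n) stop("length(sigma2) must equal length(y)")
    if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
      stop("all sampling variances must be positive and finite")
  }
  if (!is.null(adjacency)) {
    if (!inherits(adjacency, "adjacency"))
      adjacency <- build_adjacency(adjacency)
    if (adjacency$n != n)
      stop("adjacency has ", adjacency$n, " areas but data has ", n)
    if (!all(adjacency$ids %in% ids) && !all(adjacency$ids == as.character(seq_len(n))))
      stop("adjacency ids do not match dataset ids")
  }
  structure(list(y = y, X = X, sigma2 = sigma2, adjacency = adjacency,
                 ids = ids, n = n, p = ncol(X) - 1L),
            class = "area_dataset")
}

#' @export
print.area_dataset <- function(x, ...) {
  cat(sprintf("Areal dataset: %d areas, %d covariate(s)%s%s\n",
              x$n, x$p,
              if (is.null(x$sigma2)) ", sampling variances not supplied"
              else ", per-area sampling variances",
              if (is.null(x$adjacency)) ", no adjacency" else ""))
  invisible(x)
}

#' Read an areal data table from CSV
#'
#' Either a ready response column, or observed and expected count columns
#' from which the log SIR is computed with the continuity correction
#' \eqn{y = \log\{(O + 0.5)/(E + 0.5)\}}.
#'
#' @param path CSV file with a header row.
#' @param id column name holding the area identifier.
#' @param response column name of the continuous response, or NULL when
#'   counts are given.
#' @param observed,expected count column names (used when \code{response}
#'   is NULL).
#' @param covariates character vector of covariate column names.
#' @param variance optional column name of per-area sampling variances.
#' @param adjacency optional adjacency input forwarded to
#'   \code{\link{area_dataset}}.
#' @return An \code{"area_dataset"}.
#' @export
read_area_table <- function(path, id = "id", response = "y",
                            observed = "observed", expected = "expected",
                            covariates = character(), variance = NULL,
                            adjacency = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(id, covariates, variance,
            if (!is.null(response)) response else c(observed, expected))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(df[[id]])
  if (anyDuplicated(ids))
    stop("duplicate area id: ", ids[duplicated(ids)][1])
  num <- function(col) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing value in column '", col,
           "' for area id ", ids[bad[1]])
    v
  }
  if (!is.null(response)) {
    y <- num(response)
  } else {
    O <- num(observed); E <- num(expected)
    bad <- which(E <= 0)
    if (length(bad))
      stop("non-positive expected count for area id ", ids[bad[1]])
    y <- log((O + 0.5) / (E + 0.5))
  }
  X <- if (length(covariates))
    cbind(1, as.matrix(sapply(covariates, num)))
  else matrix(1, nrow(df), 1)
  colnames(X) <- c("(Intercept)", covariates)
  sigma2 <- if (!is.null(variance)) num(variance) else NULL
  area_dataset(y, X, adjacency = adjacency, sigma2 = sigma2, ids = ids)
}

#' Write an areal dataset to CSV
#'
#' Inverse of \code{\link{read_area_table}} for the response form; the
#' adjacency is not included (see \code{\link{write_gal}}).
#'
#' @param data an \code{"area_dataset"}.
#' @param path output CSV path.
#' @export
write_area_table <- function(data, path) {
  stopifnot(inherits(data, "area_dataset"))
  df <- data.frame(id = data$ids, y = data$y, check.names = FALSE)
  if (data$p > 0) {
    cov <- data$X[, -1, drop = FALSE]
    df <- cbind(df, as.data.frame(cov, optional = TRUE))
  }
  if (!is.null(data$sigma2)) df$variance <- data$sigma2
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
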