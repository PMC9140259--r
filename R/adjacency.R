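#' Build an areal adjacency structure
#'
#' Accepts a binary symmetric matrix, a two-column edge list (data frame or
#' matrix of area ids / indices), or the path of a GAL spatial-weights file,
#' and returns the validated neighbourhood structure used by the CAR priors.
#'
#' @param x adjacency input: n x n binary matrix, two-column edge list, or a
#'   single string naming a GAL file.
#' @param n_areas number of areas; required for an edge list given as plain
#'   integer indices (otherwise inferred).
#' @param ids optional character vector of area identifiers.
#' @return An object of class \code{"adjacency"}: list with the binary
#'   matrix \code{B}, neighbour counts \code{n_nb}, \code{n}, \code{ids},
#'   logical \code{connected} and \code{n_components}.
#' @examples
#' a <- build_adjacency(cbind(c(1, 2), c(2, 3)), n_areas = 3)
#' a$n_nb  # 1 2 1
#' @export
build_adjacency <- function(x, n_areas = NULL, ids = NULL) {
  if (is.character(x) && length(x) == 1L) return(read_gal(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("adjacency input must be a matrix, edge list or GAL path")

  # a two-column matrix is an edge list only if it plausibly holds area
  # ids (characters or positive integers); otherwise it is validated as a
  # square adjacency matrix
  looks_like_edges <- ncol(x) == 2L &&
    (is.character(x) || all(x >= 1 & x == round(x))) &&
    !(nrow(x) == 2L && !is.character(x) && all(x %in% c(0, 1)) &&
      all(diag(x) == 0) && isSymmetric(unname(x)) &&
      (is.null(n_areas) || n_areas == 2L))
  if (looks_like_edges) {
    # edge list
    if (is.character(x)) {
      if (is.null(ids)) ids <- sort(unique(as.vector(x)))
      idx <- matrix(match(x, ids), ncol = 2L)
      if (anyNA(idx)) stop("edge list refers to unknown area id")
      n <- length(ids)
    } else {
      idx <- x
      n <- if (is.null(n_areas)) max(idx) else as.integer(n_areas)
      if (any(idx < 1 | idx > n)) stop("edge list refers to unknown area id")
    }
    if (any(idx[, 1] == idx[, 2])) stop("self-loop in edge list")
    B <- matrix(0, n, n)
    B[idx] <- 1
    B[idx[, c(2, 1), drop = FALSE]] <- 1
  } else {
    B <- x
    n <- nrow(B)
    if (ncol(B) != n) stop("adjacency matrix must be square")
    if (!all(B %in% c(0, 1))) stop("adjacency matrix entries must be 0/1")
    if (any(diag(B) != 0)) stop("adjacency matrix must have zero diagonal (no self-loops)")
    if (!isSymmetric(unname(B))) stop("adjacency matrix must be symmetric")
    if (!is.null(rownames(B)) && is.null(ids)) ids <- rownames(B)
  }
  dimnames(B) <- NULL
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(ids) != n) stop("length(ids) must equal number of areas")
  .finish_adjacency(B, ids)
}

.finish_adjacency <- function(B, ids) {
  n <- nrow(B)
  n_nb <- as.integer(rowSums(B))
  comp <- .graph_components(B)
  if (any(n_nb == 0))
    warning("isolated area(s) with no neighbours: ",
            paste(ids[n_nb == 0], collapse = ", "))
  structure(list(B = B, n_nb = n_nb, n = n, ids = ids,
                 connected = max(comp) == 1L, n_components = max(comp),
                 component = comp),
            class = "adjacency")
}

# connected components by breadth-first traversal
.graph_components <- function(B) {
  n <- nrow(B)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(B[v, ] == 1 & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("Adjacency: %d areas, %d undirected edges, %s\n",
              x$n, sum(x$B) / 2,
              if (x$connected) "connected"
              else sprintf("%d components", x$n_components)))
  invisible(x)
}

#' Read / write GAL spatial-weights files
#'
#' The GAL dialect used is the libpysal-compatible one: a header line whose
#' last-but-two field is the number of areas, then for each area a line
#' \code{id n_neighbours} followed by a line listing the neighbour ids.
#'
#' @param path file path.
#' @return \code{read_gal} returns an \code{"adjacency"} object.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  # libpysal headers are "0 n file var" or just "n"
  n <- as.integer(if (length(hdr) >= 2) hdr[2] else hdr[1])
  if (is.na(n) || n < 1) stop("cannot parse GAL header: ", lines[1])
  ids <- character(n); nbrs <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    head_i <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[i] <- head_i[1]
    k <- as.integer(head_i[2])
    if (k > 0) {
      nbrs[[i]] <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
      if (length(nbrs[[i]]) != k)
        stop("GAL neighbour count mismatch for area ", ids[i])
      pos <- pos + 2L
    } else {
      nbrs[[i]] <- character(0)
      pos <- pos + if (length(lines) >= pos + 1L &&
                       !nzchar(trimws(lines[pos + 1L]))) 2L else 1L
      # zero-neighbour areas may or may not carry an empty line; tolerate both
      if (pos <= length(lines)) {
        nxt <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
        if (length(nxt) == 0 || !nzchar(nxt[1])) pos <- pos + 1L
      }
    }
  }
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- match(nbrs[[i]], ids)
    if (anyNA(j)) stop("GAL file refers to unknown area id for area ", ids[i])
    B[i, j] <- 1
  }
  if (!isSymmetric(B)) stop("GAL file encodes an asymmetric neighbour relation")
  .finish_adjacency(B, ids)
}

#' @rdname read_gal
#' @param adj an \code{"adjacency"} object.
#' @export
write_gal <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("0 %d unknown unknown", adj$n), con)
  for (i in seq_len(adj$n)) {
    nb <- which(adj$B[i, ] == 1)
    writeLines(sprintf("%s %d", adj$ids[i], length(nb)), con)
    writeLines(paste(adj$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Rook-adjacency square lattice
#'
#' @param side lattice side length (>= 2); gives \code{side^2} areas.
#' @return An \code{"adjacency"} object for the side x side rook lattice.
#' @examples
#' make_lattice(5)$n  # 25
#' @export
make_lattice <- function(side) {
  side <- as.integer(side)
  if (is.na(side) || side < 2L) stop("'side' must be an integer >= 2")
  n <- side * side
  B <- matrix(0, n, n)
  idx <- function(r, c) (r - 1L) * side + c
  for (r in seq_len(side)) for (c in seq_len(side)) {
    i <- idx(r, c)
    if (c < side) { j <- idx(r, c + 1L); B[i, j] <- B[j, i] <- 1 }
    if (r < side) { j <- idx(r + 1L, c); B[i, j] <- B[j, i] <- 1 }
  }
  .finish_adjacency(B, as.character(seq_len(n)))
}

#' Intrinsic autoregression matrix
#'
#' Returns the matrix \eqn{R} with \eqn{R_{ii} = n_i} (neighbour count) and
#' \eqn{R_{ij} = -1} when areas i and j are adjacent: the precision kernel of
#' the intrinsic CAR prior and the building block of the Leroux family.
#'
#' @param adj an \code{"adjacency"} object.
#' @return n x n symmetric positive semi-definite matrix with zero row sums.
#' @export
intrinsic_R <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  diag(adj$n_nb) - adj$B
}

#' Leroux generalised-inverse structure matrix
#'
#' \eqn{D^-(\rho) = (1-\rho) I + \rho R}: the prior precision of the spatial
#' random effects is \eqn{\tau D^-}. \eqn{\rho = 0} gives independence,
#' \eqn{\rho = 1} the intrinsic autoregression.
#'
#' @param R intrinsic autoregression matrix from \code{\link{intrinsic_R}}.
#' @param rho spatial mixing parameter in [0, 1].
#' @export
leroux_Dminus <- function(R, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]")
  (1 - rho) * diag(nrow(R)) + rho * R
}

#' Generalised Moran eigenvector basis
#'
#' Residualises the adjacency operator against the design matrix,
#' \eqn{P_c = I - X(X'X)^{-1}X'}, eigendecomposes \eqn{P_c B P_c} and keeps
#' the eigenvectors with positive eigenvalues (positive spatial
#' autocorrelation patterns orthogonal to the covariates). The reduced
#' random effect is \eqn{\psi = M \psi^*} with prior precision
#' \eqn{\tau\, M'(B_+ - B) M}.
#'
#' @param adj an \code{"adjacency"} object.
#' @param X design matrix (full column rank).
#' @param tol relative eigenvalue cutoff: eigenvalues above
#'   \code{tol * max(eigenvalue)} count as positive.
#' @return list with orthonormal basis \code{M} (n x q), \code{q}, and
#'   \code{moran_precision} = \eqn{M'(B_+ - B)M}.
#' @export
moran_basis <- function(adj, X, tol = 1e-8) {
  stopifnot(inherits(adj, "adjacency"))
  X <- as.matrix(X)
  if (nrow(X) != adj$n) stop("nrow(X) must equal number of areas")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  Pc <- diag(adj$n) - X %*% solve(crossprod(X), t(X))
  op <- Pc %*% adj$B %*% Pc
  op <- (op + t(op)) / 2
  es <- eigen(op, symmetric = TRUE)
  cutoff <- tol * max(es$values)
  keep <- which(es$values > cutoff)
  M <- es$vectors[, keep, drop = FALSE]
  R <- intrinsic_R(adj)   # B_+ - B
  mp <- crossprod(M, R %*% M)
  mp <- (mp + t(mp)) / 2
  list(M = M, q = length(keep), moran_precision = mp,
       eigenvalues = es$values)
}

#' Leroux full-conditional moments (closed form)
#'
#' The univariate full conditional of one area's random effect under the
#' Leroux prior: mean \eqn{\rho \sum_{j\sim i}\psi_j / (n_i\rho + 1 - \rho)}
#' and variance \eqn{\sigma^2 / (n_i\rho + 1 - \rho)}. Used as an analytic
#' oracle for the joint Gaussian defined by \eqn{\tau D^-}.
#'
#' @param psi random-effect vector.
#' @param i area index.
#' @param rho mixing parameter in [0, 1].
#' @param sigma2 prior variance parameter (\eqn{1/\tau}).
#' @param adj an \code{"adjacency"} object.
#' @return list with \code{mean} and \code{variance}.
#' @export
conditional_moments_leroux <- function(psi, i, rho, sigma2, adj) {
  stopifnot(inherits(adj, "adjacency"))
  ni <- adj$n_nb[i]
  denom <- ni * rho + 1 - rho
  nb_sum <- sum(psi[adj$B[i, ] == 1])
  list(mean = rho * nb_sum / denom, variance = sigma2 / denom)
}
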