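#' Load a binned intra-chromosomal contact matrix from a triplet dump
#'
#' Reads a plain-text triplet file with rows `pos1 pos2 value`
#' (tab/space separated), where positions are bin-start coordinates
#' (0-based multiples of the resolution). The matrix is stored
#' symmetrically; duplicated ordered pairs are summed.
#'
#' @param path triplet file.
#' @param chrom chromosome name.
#' @param resolution bin size in bp (default 5000).
#' @param n_bins number of bins; defaults to the largest bin present + 1.
#'   Pass `ceiling(chrom_size / resolution)` to fix the dimension.
#' @return an object of class `contact_matrix` with elements `chrom`,
#'   `resolution`, `n_bins`, `counts` (sparse symmetric `Matrix`),
#'   `balanced` (`NULL` until [kr_balance()]), `scaling`, `masked_bins`
#'   (0-based indices of all-zero bins).
#' @export
load_contact_triplets <- function(path, chrom, resolution = 5000,
                                  n_bins = NULL) {
  if (!file.exists(path)) stop("triplet file not found: ", path)
  if (file.size(path) == 0) {
    tri <- data.frame(p1 = numeric(0), p2 = numeric(0), v = numeric(0))
  } else {
    raw <- scan(path, what = list(p1 = numeric(0), p2 = numeric(0),
                                  v = numeric(0)), quiet = TRUE)
    tri <- as.data.frame(raw)
  }
  if (nrow(tri) > 0) {
    if (any(tri$p1 %% resolution != 0 | tri$p2 %% resolution != 0)) {
      stop("position not a multiple of resolution (", resolution,
           ") in ", path)
    }
    if (any(tri$v < 0)) stop("negative contact value in ", path)
    if (any(tri$p1 < 0 | tri$p2 < 0)) stop("negative position in ", path)
  }
  b1 <- tri$p1 %/% resolution
  b2 <- tri$p2 %/% resolution
  if (is.null(n_bins)) {
    n_bins <- if (nrow(tri) > 0) max(b1, b2) + 1 else 0L
  }
  n_bins <- as.integer(n_bins)
  if (nrow(tri) > 0 && max(b1, b2) >= n_bins) {
    stop("bin index beyond n_bins in ", path)
  }
  # mirror off-diagonal entries so the stored matrix is symmetric
  off <- b1 != b2
  i <- c(b1, b2[off]) + 1L
  j <- c(b2, b1[off]) + 1L
  x <- c(tri$v, tri$v[off])
  counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(n_bins, n_bins))
  .new_contact_matrix(chrom, resolution, n_bins, counts)
}

#' Construct a contact matrix from an in-memory symmetric matrix
#' @param m symmetric non-negative matrix (base or `Matrix`).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @return a `contact_matrix`.
#' @export
contact_matrix_from_dense <- function(m, chrom = "chr1", resolution = 5000) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (!Matrix::isSymmetric(m)) stop("contact matrix must be symmetric")
  if (any(m@x < 0)) stop("contact matrix must be non-negative")
  .new_contact_matrix(chrom, resolution, nrow(m), m)
}

.new_contact_matrix <- function(chrom, resolution, n_bins, counts) {
  rs <- Matrix::rowSums(counts)
  structure(list(chrom = chrom, resolution = resolution,
                 n_bins = as.integer(n_bins), counts = counts,
                 balanced = NULL, scaling = rep(NA_real_, n_bins),
                 masked_bins = which(rs == 0) - 1L),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix", x$chrom, "@", x$resolution, "bp:", x$n_bins,
      "bins,", length(x$counts@x), "stored entries,",
      length(x$masked_bins), "masked,",
      if (is.null(x$balanced)) "raw\n" else "balanced\n")
  invisible(x)
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Finds the diagonal scaling `D` such that every unmasked row of
#' `D A D` has equal sum (normalized to 1), the standard Hi-C matrix
#' normalization. Uses the Knight-Ruiz Newton iteration with an inner
#' conjugate-gradient solve; if that fails to converge within `max_iter`
#' matrix-vector products, falls back to symmetric Sinkhorn-Knopp
#' alternating scaling. All-zero rows are masked and left unscaled.
#'
#' @param m a `contact_matrix`.
#' @param tol relative tolerance on row sums (default 1e-6).
#' @param max_iter iteration budget (default 3000).
#' @return the `contact_matrix` with `balanced` and `scaling` filled in.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$n_bins
  keep <- setdiff(seq_len(n), m$masked_bins + 1L)
  scaling <- rep(NA_real_, n)
  if (length(keep) == 0) {
    m$balanced <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(n, n))
    m$scaling <- scaling
    return(m)
  }
  A <- m$counts[keep, keep, drop = FALSE]
  x <- .kr_newton(A, tol = tol, max_iter = max_iter)
  if (is.null(x)) {
    x <- .sinkhorn_symmetric(A, tol = tol, max_iter = max_iter)
  }
  if (is.null(x)) {
    r <- as.numeric(A %*% rep(1, nrow(A)))
    stop("matrix balancing did not converge (row-sum CV residual ",
         format(stats::sd(r) / mean(r)), ")")
  }
  scaling[keep] <- x
  D <- Matrix::Diagonal(x = ifelse(is.na(scaling), 0, scaling))
  m$balanced <- methods::as(D %*% m$counts %*% D, "CsparseMatrix")
  m$scaling <- scaling
  m
}

# Knight & Ruiz (2013)-style balancing: Newton outer iteration with an
# inner CG solve, seeking x with x * (A x) = 1. Returns NULL on failure.
.kr_newton <- function(A, tol = 1e-6, max_iter = 3000,
                       delta = 0.1, Delta = 3) {
  n <- nrow(A)
  if (n == 1) return(1 / sqrt(A[1, 1]))
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (!is.finite(rho_km1)) return(NULL)
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    if (mvp > max_iter) return(NULL)
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# Symmetric Sinkhorn-Knopp: x <- sqrt(x / (A x)); fixed point satisfies
# x * (A x) = 1. Used as the fallback and, in tests, as the oracle.
.sinkhorn_symmetric <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- as.numeric(A %*% x)
    if (any(r <= 0)) return(NULL)
    x <- sqrt(x / r)
    s <- x * as.numeric(A %*% x)
    cv <- stats::sd(s) / mean(s)
    if (is.finite(cv) && cv < tol * 0.5) return(x)
  }
  NULL
}

#' Balanced contact frequency between two genomic positions
#'
#' Looks up the Knight-Ruiz-balanced contact between the bins containing
#' two positions on the matrix chromosome. Masked bins and absent pairs
#' return 0; the lookup is symmetric in its arguments, and a same-bin
#' query returns the diagonal entry.
#'
#' @param m a balanced `contact_matrix`.
#' @param pos_a,pos_b positions in bp (0-based offsets; vectorized).
#' @return numeric vector of contact frequencies.
#' @export
contact <- function(m, pos_a, pos_b) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is.null(m$balanced)) stop("contact matrix is not balanced yet; run kr_balance()")
  if (length(pos_a) != length(pos_b)) {
    stop("pos_a and pos_b must have equal length")
  }
  ba <- pos_a %/% m$resolution + 1
  bb <- pos_b %/% m$resolution + 1
  out <- numeric(length(ba))
  ok <- ba >= 1 & ba <= m$n_bins & bb >= 1 & bb <= m$n_bins
  if (any(ok)) {
    out[ok] <- m$balanced[cbind(ba[ok], bb[ok])]
  }
  out
}

#' Write a contact matrix as a triplet dump
#'
#' Emits the upper triangle (including the diagonal) as
#' `pos1 pos2 value` rows with 0-based bin-start positions.
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @param balanced write balanced values instead of raw counts.
#' @return `path`, invisibly.
#' @export
write_contact_triplets <- function(m, path, balanced = FALSE) {
  mat <- if (balanced) {
    if (is.null(m$balanced)) stop("matrix not balanced")
    m$balanced
  } else {
    m$counts
  }
  tm <- methods::as(methods::as(mat, "generalMatrix"), "TsparseMatrix")
  sel <- tm@i <= tm@j
  df <- data.frame(p1 = (tm@i[sel]) * m$resolution,
                   p2 = (tm@j[sel]) * m$resolution,
                   v = tm@x[sel])
  df <- df[order(df$p1, df$p2), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
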