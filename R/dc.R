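#' Fit a worker-side intermediate (dimension-reduction) map
#'
#' Each worker compresses its private data \eqn{X_i \in R^{m_i \times d}} to
#' an intermediate representation \eqn{\tilde{X}_i = f_i(X_i) \in R^{m_i
#' \times l}} with \eqn{l < d} before anything leaves the institution. Two
#' linear maps are supported: `"pca"` (centre by column means, project on the
#' top-l principal directions) and `"svd"` (no centring, top-l right singular
#' vectors). Columns of the projection are orthonormal; each is oriented so
#' its largest-magnitude entry is positive, making the map deterministic
#' across runs and platforms.
#'
#' @param X Numeric matrix (samples x features).
#' @param method `"pca"` or `"svd"`.
#' @param l Target dimension, `1 <= l < ncol(X)`.
#' @param scale. If `TRUE`, columns are also divided by their standard
#'   deviation before projection (PCA on the correlation scale). The
#'   default `FALSE` is classical covariance PCA; the high-level pipeline
#'   turns scaling on because the encoded clinical features mix units whose
#'   variances differ by three orders of magnitude, and unscaled principal
#'   directions would be dominated by the numerically largest columns.
#' @param fitted_on Optional worker label recorded on the map.
#' @return An `intermediate_map`: list with `method`, `l`, `d`, `center`
#'   (zero vector for `"svd"`), `scale` (ones when unscaled), and `P`
#'   (`d x l`, orthonormal columns).
#' @export
fit_intermediate_map <- function(X, method = c("pca", "svd"), l,
                                 scale. = FALSE, fitted_on = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  d <- ncol(X)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  assert_scalar_number(l, "l")
  if (l < 1) stop("l must be >= 1", call. = FALSE)
  if (l >= d) {
    stop("the intermediate dimension must satisfy l < d (got l = ", l,
         ", d = ", d, ")", call. = FALSE)
  }
  center <- if (method == "pca") colMeans(X) else rep(0, d)
  scl <- rep(1, d)
  if (isTRUE(scale.)) {
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1   # constant columns pass through
  }
  Xc <- sweep(sweep(X, 2, center), 2, scl, "/")
  sv <- svd(Xc, nu = 0, nv = l)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  if (sum(sv$d > tol) < l) {
    stop("data rank ", sum(sv$d > tol), " is below the requested l = ", l,
         call. = FALSE)
  }
  structure(
    list(method = method, l = as.integer(l), d = d,
         center = unname(center), scale = unname(scl), P = fix_signs(sv$v),
         fitted_on = fitted_on),
    class = "intermediate_map"
  )
}

# Deterministic orientation: make the largest-magnitude entry of each
# column positive (first index wins ties).
fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Apply an intermediate map to data or anchors
#'
#' Computes \eqn{(X - \bar{x}) P}, the worker's compression, applied
#' identically to the worker's own samples and to the shared anchor matrix.
#'
#' @param f An `intermediate_map` from [fit_intermediate_map()].
#' @param X Numeric matrix with `ncol(X) == f$d` (an [generate_anchor()]
#'   result is also accepted).
#' @return An `nrow(X) x f$l` matrix.
#' @export
apply_map <- function(f, X) {
  stopifnot(inherits(f, "intermediate_map"))
  if (inherits(X, "anchor_data")) X <- X$A
  X <- as.matrix(X)
  if (ncol(X) != f$d) {
    stop("dimension mismatch: map expects d = ", f$d, ", got ", ncol(X),
         call. = FALSE)
  }
  Xc <- sweep(X, 2, f$center)
  if (!is.null(f$scale) && any(f$scale != 1)) {
    Xc <- sweep(Xc, 2, f$scale, "/")
  }
  Xc %*% f$P
}

#' Generate shared anchor data
#'
#' The anchor matrix \eqn{X^{anc} \in R^{r \times d}} is an artificial
#' reference shared identically by all workers: each worker pushes it
#' through its own compression, and the master aligns the images. Two
#' strategies are provided: `"uniform"` draws every entry independently from
#' the feature's public reference interval (a plain random-number matrix);
#' `"resample"` interpolates random convex combinations of pairs of rows of
#' a supplied public reference table (a SMOTE-style construction). Neither
#' touches any worker's private data.
#'
#' @param bounds Named list of per-feature `c(lo, hi)` intervals (one entry
#'   per encoded column), e.g. from [anchor_bounds()]. Required for
#'   `"uniform"`.
#' @param r Number of anchor rows.
#' @param strategy `"uniform"` or `"resample"`.
#' @param reference Public reference matrix for `"resample"` (columns in the
#'   same encoded order).
#' @param seed Integer seed; identical seeds give identical anchors.
#' @return An `anchor_data` object: list with matrix `A` (`r x d`),
#'   `strategy`, `seed`, `feature_names`.
#' @export
generate_anchor <- function(bounds = NULL, r = 1000,
                            strategy = c("uniform", "resample"),
                            reference = NULL, seed = 1) {
  strategy <- match.arg(strategy)
  assert_scalar_number(r, "r")
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (strategy == "uniform") {
    if (is.null(bounds)) stop("uniform anchors need bounds", call. = FALSE)
    bad <- vapply(bounds, function(b) length(b) != 2 || b[1] >= b[2],
                  logical(1))
    if (any(bad)) {
      stop("invalid bounds (need lo < hi) for: ",
           paste(names(bounds)[bad], collapse = ", "), call. = FALSE)
    }
    d <- length(bounds)
    A <- vapply(bounds, function(b) stats::runif(r, b[1], b[2]),
                numeric(r))
    A <- matrix(A, nrow = r, dimnames = list(NULL, names(bounds)))
  } else {
    if (is.null(reference)) {
      stop("resample anchors need a public reference table", call. = FALSE)
    }
    reference <- as.matrix(reference)
    i <- sample.int(nrow(reference), r, replace = TRUE)
    j <- sample.int(nrow(reference), r, replace = TRUE)
    w <- stats::runif(r)
    A <- w * reference[i, , drop = FALSE] +
      (1 - w) * reference[j, , drop = FALSE]
  }
  structure(list(A = A, strategy = strategy, seed = seed,
                 feature_names = colnames(A)),
            class = "anchor_data")
}

#' Anchor bounds for a set of encoded feature columns
#'
#' Maps encoded column names (`HbA1c_2014`, `Sex`, `Age`, ...) back to their
#' base feature and returns the public reference interval for each, for use
#' with the `"uniform"` anchor strategy.
#'
#' @param feature_names Encoded column names as produced by
#'   [encode_features()].
#' @param ranges Named list of base-feature intervals; defaults to
#'   [default_reference_ranges()].
#' @return Named list of `c(lo, hi)` per encoded column.
#' @export
anchor_bounds <- function(feature_names, ranges = default_reference_ranges()) {
  base <- sub("_[0-9]{4}$", "", feature_names)
  missing <- setdiff(unique(base), names(ranges))
  if (length(missing)) {
    stop("no reference range for feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::setNames(ranges[base], feature_names)
}

#' Master-side collaboration maps from anchor images
#'
#' Given the anchor images \eqn{\tilde{X}_i^{anc} = f_i(X^{anc})} shared by
#' the workers, the master chooses a common target and solves, per worker,
#' the least-squares alignment so that the re-projected anchors nearly
#' coincide: \eqn{\hat{X}_i^{anc} \approx \hat{X}_j^{anc}}. The target
#' \eqn{Z \in R^{r \times k}} is taken as the top-k left singular vectors of
#' the concatenation \eqn{[\tilde{X}_1^{anc} | \cdots | \tilde{X}_n^{anc}]},
#' and each reconversion matrix solves \eqn{G_i = \arg\min_G
#' \|\tilde{X}_i^{anc} G - Z\|_F}.
#'
#' @param anchor_intermediates List of `r x l_i` matrices, one per worker
#'   (all sharing the same `r`).
#' @param k Integrated dimension, `k <= min(l_i)`; defaults to `min(l_i)`.
#' @return A `collaboration_maps` object: list with `maps` (list of `l_i x
#'   k` matrices `G_i`), the shared orthonormal target `Z`, and `k`.
#' @export
compute_collaboration_maps <- function(anchor_intermediates, k = NULL) {
  stopifnot(is.list(anchor_intermediates), length(anchor_intermediates) >= 1)
  mats <- lapply(anchor_intermediates, as.matrix)
  r <- unique(vapply(mats, nrow, integer(1)))
  if (length(r) != 1) {
    stop("all anchor intermediates must share the anchor count r",
         call. = FALSE)
  }
  ls <- vapply(mats, ncol, integer(1))
  k <- k %||% min(ls)
  assert_scalar_number(k, "k")
  if (k > min(ls)) {
    stop("k = ", k, " exceeds the smallest intermediate dimension ",
         min(ls), call. = FALSE)
  }
  for (i in seq_along(mats)) {
    sv <- svd(mats[[i]], nu = 0, nv = 0)
    tol <- max(dim(mats[[i]])) * .Machine$double.eps * sv$d[1]
    rk <- sum(sv$d > tol)
    if (rk < k) {
      stop("worker ", i, " anchor intermediate has rank ", rk,
           " < k = ", k, "; reduce k or enrich the anchors", call. = FALSE)
    }
  }
  C <- do.call(cbind, mats)
  sv <- svd(C, nu = k, nv = 0)
  Z <- fix_signs(sv$u)
  maps <- lapply(mats, function(A) qr.solve(A, Z))
  structure(list(maps = maps, Z = Z, k = as.integer(k), r = r),
            class = "collaboration_maps")
}

#' @export
print.collaboration_maps <- function(x, ...) {
  cat("<collaboration_maps> ", length(x$maps), " worker(s), k = ", x$k,
      ", r = ", x$r, " anchors\n", sep = "")
  invisible(x)
}

#' Stack worker data into the collaborative representation
#'
#' Applies each worker's own compression and the master's reconversion,
#' \eqn{\hat{X}_i = f_i(X_i) G_i}, and stacks the results sample-wise into a
#' single `(sum(m_i)) x k` dataset on which one model is trained.
#'
#' @param datasets List of `labeled_dataset`s (or plain lists with `X`, `y`),
#'   one per worker, all with the same feature dimension.
#' @param f_maps List of `intermediate_map`s, one per worker.
#' @param g_maps A `collaboration_maps` object from
#'   [compute_collaboration_maps()].
#' @return A `collaborative_dataset`: list with `X` (stacked matrix), `y`,
#'   `provenance` (worker label per row), `k`.
#' @export
build_collaborative_dataset <- function(datasets, f_maps, g_maps) {
  stopifnot(inherits(g_maps, "collaboration_maps"),
            length(datasets) == length(f_maps),
            length(datasets) == length(g_maps$maps))
  d <- unique(vapply(f_maps, function(f) f$d, integer(1)))
  if (length(d) != 1) stop("workers disagree on the feature dimension d",
                           call. = FALSE)
  ks <- vapply(g_maps$maps, ncol, integer(1))
  if (any(ks != g_maps$k)) stop("mismatched k across collaboration maps",
                                call. = FALSE)
  blocks <- vector("list", length(datasets))
  ys <- vector("list", length(datasets))
  prov <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    blocks[[i]] <- apply_map(f_maps[[i]], ds$X) %*% g_maps$maps[[i]]
    ys[[i]] <- ds$y
    who <- ds$institution %||% paste0("worker", i)
    prov[[i]] <- rep(who, nrow(ds$X))
  }
  structure(
    list(X = do.call(rbind, blocks), y = unname(unlist(ys)),
         provenance = unlist(prov), k = g_maps$k),
    class = "collaborative_dataset"
  )
}

#' @export
print.collaborative_dataset <- function(x, ...) {
  cat("<collaborative_dataset> ", nrow(x$X), " samples x ", x$k,
      " dims from ", length(unique(x$provenance)), " worker(s)\n", sep = "")
  invisible(x)
}

#' Pairwise anchor alignment residual
#'
#' Diagnostic for collaboration quality: \eqn{\sum_{i<j}
#' \|\tilde{X}_i^{anc} G_i - \tilde{X}_j^{anc} G_j\|_F}. Zero for a single
#' worker or for workers with identical maps; small residuals mean the
#' re-projected anchors nearly coincide.
#'
#' @param g_maps A `collaboration_maps` object.
#' @param anchor_intermediates The same list passed to
#'   [compute_collaboration_maps()].
#' @return Nonnegative scalar.
#' @export
anchor_alignment_residual <- function(g_maps, anchor_intermediates) {
  stopifnot(inherits(g_maps, "collaboration_maps"))
  hats <- Map(function(A, G) as.matrix(A) %*% G,
              anchor_intermediates, g_maps$maps)
  n <- length(hats)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sqrt(sum((hats[[i]] - hats[[j]])^2))
    }
  }
  tot
}

#' Worker role: produce the shareable representation
#'
#' Fits the worker's private compression and returns two parts: `share`,
#' the only object transmitted to the master (intermediate data, anchor
#' image, labels, worker name — never the raw `X`), and `map`, which stays
#' at the institution (needed locally, e.g. to transform future test
#' samples).
#'
#' @param dataset A `labeled_dataset`.
#' @param anchor Shared `anchor_data`.
#' @param method,l,scale. Passed to [fit_intermediate_map()]; `l` defaults
#'   to `min(d - 1, ceiling(0.75 * d))` and scaling is on by default (the
#'   encoded clinical columns mix units).
#' @return List with `share` (class `worker_share`) and `map`.
#' @export
worker_encode <- function(dataset, anchor, method = "pca", l = NULL,
                          scale. = TRUE) {
  d <- ncol(dataset$X)
  l <- l %||% default_intermediate_dim(d)
  f <- fit_intermediate_map(dataset$X, method, l, scale. = scale.,
                            fitted_on = dataset$institution)
  share <- structure(
    list(intermediate = apply_map(f, dataset$X),
         anchor_intermediate = apply_map(f, anchor),
         y = dataset$y, worker = dataset$institution %||% "worker"),
    class = "worker_share"
  )
  list(share = share, map = f)
}

default_intermediate_dim <- function(d) min(d - 1L, as.integer(ceiling(0.75 * d)))

#' Master role: align shares into one collaborative dataset
#'
#' Accepts only the workers' shares (intermediate representations, anchor
#' images, labels) — the raw data never reach the master. Computes the
#' collaboration maps and stacks the re-projected representations.
#'
#' @param shares List of `worker_share` objects from [worker_encode()].
#' @param k Integrated dimension; defaults to the smallest worker dimension.
#' @return List with `collab` (a `collaborative_dataset`), `g_maps`, and the
#'   anchor alignment `residual`.
#' @export
master_collaborate <- function(shares, k = NULL) {
  stopifnot(all(vapply(shares, inherits, logical(1), "worker_share")))
  anchors <- lapply(shares, `[[`, "anchor_intermediate")
  g <- compute_collaboration_maps(anchors, k)
  blocks <- Map(function(s, G) s$intermediate %*% G, shares, g$maps)
  collab <- structure(
    list(X = do.call(rbind, blocks),
         y = unname(unlist(lapply(shares, `[[`, "y"))),
         provenance = unlist(Map(function(s, b) rep(s$worker, nrow(b)),
                                 shares, blocks)),
         k = g$k),
    class = "collaborative_dataset"
  )
  list(collab = collab, g_maps = g,
       residual = anchor_alignment_residual(g, anchors))
}
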