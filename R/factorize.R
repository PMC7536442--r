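# Non-negative matrix factorisation of the stacked pixels x bins matrix,
# segmentation into molecularly distinct regions, per-component signature
# ion ranking, and rank selection diagnostics.

.nndsvd_init <- function(X, k, eps = 1e-9) {
  # deterministic SVD-based nonnegative initialisation: leading singular
  # pair taken directly, later pairs split into their positive and
  # negative parts with the larger-energy pair kept
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k); H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npu <- sqrt(sum(up^2)); npv <- sqrt(sum(vp^2))
      nnu <- sqrt(sum(un^2)); nnv <- sqrt(sum(vn^2))
      if (npu * npv >= nnu * nnv) {
        sig <- npu * npv
        if (sig > 0) {
          W[, j] <- sqrt(s$d[j] * sig) * up / npu
          H[j, ] <- sqrt(s$d[j] * sig) * vp / npv
        }
      } else {
        sig <- nnu * nnv
        if (sig > 0) {
          W[, j] <- sqrt(s$d[j] * sig) * un / nnu
          H[j, ] <- sqrt(s$d[j] * sig) * vn / nnv
        }
      }
    }
  }
  W[W < eps] <- eps * mean(X)
  H[H < eps] <- eps * mean(X)
  list(W = W, H = H)
}

#' Non-negative matrix factorisation by multiplicative updates
#'
#' Minimises the Frobenius reconstruction error \eqn{\|X - WH\|_F} under
#' nonnegativity, with the classical Lee-Seung multiplicative updates.
#' These updates never increase the objective, and starting from a
#' deterministic NNDSVD initialisation (the default) the whole fit is
#' reproducible; with `init = "random"` the seed fixes the start.
#' On return the rows of H (the spectral signatures) are scaled to unit L2
#' norm, with the scale absorbed into the spatial scores W.
#'
#' @param X A `data_matrix` or a nonnegative numeric matrix (pixels x bins).
#' @param k Rank (number of components), `1 <= k <= min(dim(X))`.
#' @param init `"nndsvd"` (deterministic) or `"random"`.
#' @param seed Integer seed (used by random init).
#' @param max_iter Maximum update iterations (default 500).
#' @param tol Stop when the relative objective decrease falls below this
#'   (default 1e-6).
#' @return An object of class `"nmf_model"`: `W`, `H`, `k`, `seed`,
#'   `objective` (Frobenius error per iteration), `converged`,
#'   `bin_centers` and `pixel_map` when `X` is a `data_matrix`.
#' @export
nnmf <- function(X, k, init = c("nndsvd", "random"), seed = 1L,
                 max_iter = 500L, tol = 1e-6) {
  init <- match.arg(init)
  dm <- NULL
  if (inherits(X, "data_matrix")) { dm <- X; X <- X$matrix }
  stopifnot(is.matrix(X))
  if (any(X < 0)) stop("NMF input must be nonnegative")
  if (k < 1) stop("k must be >= 1")
  if (k > min(dim(X))) stop("k exceeds min(dim(X))")
  eps <- .Machine$double.eps
  if (init == "nndsvd") {
    st <- .nndsvd_init(X, k)
    W <- st$W; H <- st$H
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    W <- matrix(stats::runif(nrow(X) * k, 0, max(X)), nrow(X), k)
    H <- matrix(stats::runif(k * ncol(X), 0, 1), k, ncol(X))
  }
  obj <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((X - W %*% H)^2))
    obj <- c(obj, e)
    if (is.finite(prev) && prev > 0 && (prev - e) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- e
  }
  # move scale into W so H rows have unit L2 norm
  hn <- sqrt(rowSums(H^2))
  hn[hn == 0] <- 1
  H <- H / hn
  W <- sweep(W, 2, hn, `*`)
  structure(list(W = W, H = H, k = as.integer(k), seed = as.integer(seed),
                 init = init, objective = obj, converged = converged,
                 bin_centers = if (!is.null(dm)) dm$bin_centers,
                 pixel_map = if (!is.null(dm)) dm$pixel_map,
                 polarity = if (!is.null(dm)) dm$polarity),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf(paste0("<nmf_model> k = %d (%s init), %d pixels x %d bins, ",
                     "final error %.4g after %d iterations%s\n"),
              x$k, x$init, nrow(x$W), ncol(x$H),
              utils::tail(x$objective, 1), length(x$objective),
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Segment pixels into molecularly distinct regions
#'
#' Assigns each pixel the component with the largest spatial score; pixels
#' whose winning score is below `floor` times their total score stay
#' unassigned (label 0). Ties go to the lowest component index.
#'
#' @param model A fitted `nmf_model`.
#' @param pixel_map Data.frame `section, row, col` per matrix row (taken
#'   from the model when fitted on a `data_matrix`).
#' @param floor Majority floor in [0, 1) (default 0.5): the winning
#'   component must carry at least this share of the pixel's total score.
#' @param dims Optional `c(rows, cols, nz)` of the reconstructed grid; by
#'   default inferred from the pixel map.
#' @return An object of class `"region_map"`: `labels` (per matrix row),
#'   `label_volume` (array nz x rows x cols, 0 = unassigned), `k`.
#' @export
segment_regions <- function(model, pixel_map = model$pixel_map, floor = 0.5,
                            dims = NULL) {
  stopifnot(inherits(model, "nmf_model"), floor >= 0, floor < 1)
  W <- model$W
  tot <- rowSums(W)
  lab <- apply(W, 1, which.max)
  win <- W[cbind(seq_len(nrow(W)), lab)]
  lab[tot <= 0 | win < floor * tot] <- 0L
  vol <- NULL
  if (!is.null(pixel_map)) {
    if (is.null(dims)) {
      dims <- c(max(pixel_map$row) + 1L, max(pixel_map$col) + 1L,
                max(pixel_map$section) + 1L)
    }
    vol <- array(0L, c(dims[3], dims[1], dims[2]))
    vol[cbind(pixel_map$section + 1L, pixel_map$row + 1L,
              pixel_map$col + 1L)] <- lab
  }
  structure(list(labels = as.integer(lab), label_volume = vol,
                 k = model$k), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:x$k))
  cat("<region_map> voxels per label:\n")
  print(tab)
  invisible(x)
}

#' Rank signature ions of each component
#'
#' @param model A fitted `nmf_model` with bin centres.
#' @param top_n Number of top bins per component (default 10; capped at the
#'   number of bins).
#' @return A list (one element per component) of data.frames
#'   `mz, weight` sorted by H weight descending.
#' @export
component_ion_ranking <- function(model, top_n = 10L) {
  stopifnot(inherits(model, "nmf_model"))
  if (top_n < 1) stop("top_n must be >= 1")
  mz <- model$bin_centers
  if (is.null(mz)) mz <- seq_len(ncol(model$H))
  lapply(seq_len(model$k), function(j) {
    o <- order(model$H[j, ], decreasing = TRUE)
    o <- o[seq_len(min(top_n, length(o)))]
    data.frame(mz = mz[o], weight = model$H[j, o])
  })
}

# cosine similarity between rows of A and rows of B -> matrix
.cosine_rows <- function(A, B) {
  An <- A / pmax(sqrt(rowSums(A^2)), .Machine$double.eps)
  Bn <- B / pmax(sqrt(rowSums(B^2)), .Machine$double.eps)
  tcrossprod(An, Bn)
}

#' Optimally match estimated components to reference signatures
#'
#' NMF is identifiable only up to permutation and scale, so any comparison
#' with reference signatures must first find the best pairing. For the
#' small ranks used here the exact optimum is found by enumerating
#' permutations of the cosine-similarity matrix.
#'
#' @param H Estimated signature matrix (k x bins).
#' @param H_ref Reference signature matrix (r x bins, `r <= k`).
#' @return List: `assignment` (for each reference row, the matched
#'   component index), `cosines` (matched cosine per reference row).
#' @export
match_components <- function(H, H_ref) {
  k <- nrow(H); r <- nrow(H_ref)
  stopifnot(r <= k, k <= 8)
  S <- .cosine_rows(H_ref, H)        # r x k
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best <- NULL; best_sum <- -Inf
  for (p in perms(seq_len(k))) {
    a <- p[seq_len(r)]
    s <- sum(S[cbind(seq_len(r), a)])
    if (s > best_sum) { best_sum <- s; best <- a }
  }
  list(assignment = best, cosines = S[cbind(seq_len(r), best)])
}

#' Choose the factorisation rank
#'
#' Fits every candidate rank with several random restarts, reports the
#' reconstruction-error curve and the cross-replicate stability of the
#' signatures (mean matched cosine between replicate H matrices), and
#' chooses the largest k whose marginal relative error reduction over k-1
#' exceeds `elbow_threshold`. The full diagnostics table is returned so the
#' choice is never silent.
#'
#' @param X `data_matrix` or nonnegative matrix.
#' @param ks Candidate ranks (default 1:6).
#' @param replicates Random restarts per k (default 3).
#' @param seed Base seed; replicate r of rank k uses `seed + 1000 * k + r`.
#' @param elbow_threshold Minimum marginal error reduction, as a fraction
#'   of the rank-`min(ks)` error (default 0.05).
#' @param ... Passed to [nnmf()].
#' @return List: `k` (chosen), `diagnostics` (one row per (k, replicate)),
#'   `error_curve` (best error per k), `stability` (mean matched cosine
#'   per k).
#' @export
select_rank <- function(X, ks = 1:6, replicates = 3L, seed = 1L,
                        elbow_threshold = 0.05, ...) {
  stopifnot(all(ks >= 1))
  ks <- sort(unique(ks))
  diag_rows <- list()
  fits <- list()
  for (k in ks) {
    fits[[as.character(k)]] <- lapply(seq_len(replicates), function(r) {
      m <- nnmf(X, k, init = "random", seed = seed + 1000L * k + r, ...)
      diag_rows[[length(diag_rows) + 1L]] <<- data.frame(
        k = k, replicate = r, error = utils::tail(m$objective, 1),
        iterations = length(m$objective), converged = m$converged)
      m
    })
  }
  diagnostics <- do.call(rbind, diag_rows)
  err <- vapply(ks, function(k) {
    min(diagnostics$error[diagnostics$k == k])
  }, numeric(1))
  stability <- vapply(seq_along(ks), function(i) {
    ms <- fits[[as.character(ks[i])]]
    if (length(ms) < 2) return(1)
    pairs <- utils::combn(length(ms), 2)
    mean(apply(pairs, 2, function(p) {
      mean(match_components(ms[[p[1]]]$H, ms[[p[2]]]$H)$cosines)
    }))
  }, numeric(1))
  base_err <- err[1]
  chosen <- ks[1]
  if (length(ks) > 1) {
    for (i in 2:length(ks)) {
      if ((err[i - 1] - err[i]) / max(base_err, .Machine$double.eps) >
          elbow_threshold) {
        chosen <- ks[i]
      } else break
    }
  }
  list(k = chosen, diagnostics = diagnostics,
       error_curve = data.frame(k = ks, error = err),
       stability = data.frame(k = ks, mean_cosine = stability))
}
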