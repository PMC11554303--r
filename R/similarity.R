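#' Cosine similarity of two weight maps
#'
#' `dot(a, b) / (||a|| ||b||)` over the voxels present in both masks. A
#' value of 1 reflects proportional patterns, 0 orthogonal patterns, -1
#' patterns of opposite direction.
#'
#' @param a,b Aligned [volume_map()]s.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stop_if_misaligned(a, b)
  joint <- a$mask & b$mask
  x <- a$values[joint]
  y <- b$values[joint]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("zero-norm map: cosine similarity undefined", call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' Network-wise cosine similarity
#'
#' Cosine similarity restricted to each atlas parcel's voxels. Parcels in
#' which either map has fewer than 2 voxels or zero norm are flagged with
#' `NA` (and a warning); the remaining parcels are still returned.
#'
#' @param a,b Aligned [volume_map()]s.
#' @param atlas Integer-labelled [volume_map()] (0 = background).
#' @return Named numeric vector, one value per nonzero atlas label.
#' @export
network_similarity <- function(a, b, atlas) {
  stop_if_misaligned(a, atlas, "map and atlas")
  stop_if_misaligned(a, b)
  labels <- sort(unique(atlas$values[atlas$mask & atlas$values != 0]))
  out <- stats::setNames(rep(NA_real_, length(labels)), as.character(labels))
  degenerate <- character(0)
  for (lb in labels) {
    sel <- atlas$mask & atlas$values == lb & a$mask & b$mask
    x <- a$values[sel]; y <- b$values[sel]
    if (length(x) < 2 || sum(x^2) == 0 || sum(y^2) == 0) {
      degenerate <- c(degenerate, as.character(lb))
      next
    }
    out[as.character(lb)] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  if (length(degenerate))
    warning("degenerate network(s) flagged NA: ",
            paste(degenerate, collapse = ", "))
  out
}

# Seeded subsample of voxel pairs, binned by distance up to half the mask
# diameter. Reused across the target map and all its surrogates so their
# variograms are directly comparable.
vario_pairs <- function(coords, n_bins = 25, pairs_per_bin = 5000, seed = 1L,
                        max_frac = 0.25) {
  n <- nrow(coords)
  if (n < 100) stop("mask too small for variogram estimation (need >= 100 voxels)",
                    call. = FALSE)
  diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  max_d <- diam * max_frac
  withr::with_seed(seed, {
    m <- min(n_bins * pairs_per_bin * 3L, 400000L)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
    keep <- d <= max_d
    i <- i[keep]; j <- j[keep]; d <- d[keep]
    breaks <- seq(0, max_d, length.out = n_bins + 1)
    bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
    # cap the number of pairs per bin
    sel <- unlist(lapply(split(seq_along(bin), bin), function(ix) {
      if (length(ix) > pairs_per_bin) sample(ix, pairs_per_bin) else ix
    }), use.names = FALSE)
    bin <- bin[sel]
    ord <- order(bin)
    list(i = i[sel][ord], j = j[sel][ord], bin = bin[ord],
         bin_f = factor(bin[ord], levels = seq_len(n_bins)),
         n_per_bin = tabulate(bin, n_bins),
         centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
         n_bins = n_bins)
  })
}

# Empirical semivariance per distance bin: gamma(h) = 0.5 mean (x_i - x_j)^2.
vario_of <- function(x, pairs) {
  sq <- 0.5 * (x[pairs$i] - x[pairs$j])^2
  rs <- rowsum(sq, pairs$bin_f, reorder = FALSE)
  tot <- rep(NA_real_, pairs$n_bins)
  tot[as.integer(rownames(rs))] <- rs[, 1]
  gamma <- ifelse(pairs$n_per_bin > 0, tot / pairs$n_per_bin, NA_real_)
  list(centers = pairs$centers, semivariance = unname(gamma),
       n_pairs = pairs$n_per_bin)
}

#' Empirical variogram of a volume map
#'
#' Semivariance versus inter-voxel distance over a seeded subsample of
#' in-mask voxel pairs — the measurable footprint of a map's spatial
#' autocorrelation.
#'
#' @param map A [volume_map()].
#' @param n_bins Number of distance bins (to half the mask diameter).
#' @param pairs_per_bin Maximum sampled pairs per bin.
#' @param seed Seed for the pair subsample.
#' @return A list of class `variogram`: `centers` (mm), `semivariance`,
#'   `n_pairs`.
#' @export
variogram <- function(map, n_bins = 25, pairs_per_bin = 5000, seed = 1L) {
  stopifnot(inherits(map, "volume_map"))
  coords <- mask_coords_mm(map)
  pairs <- vario_pairs(coords, n_bins, pairs_per_bin, seed)
  structure(vario_of(mask_values(map), pairs), class = "variogram")
}

# Least-squares match of target ~ beta * candidate + alpha with both
# parameters clamped to be non-negative; bins are weighted by their pair
# counts so sparsely sampled bins do not dominate the fit.
vario_match <- function(target, candidate, weights = NULL) {
  ok <- is.finite(target) & is.finite(candidate)
  t <- target[ok]; s <- candidate[ok]
  w <- if (is.null(weights)) rep(1, length(t)) else weights[ok]
  w <- w / sum(w)
  wmean <- function(x) sum(w * x)
  fit2 <- function() {
    vs <- wmean(s^2) - wmean(s)^2
    if (vs == 0) return(c(alpha = wmean(t), beta = 0))
    beta <- (wmean(s * t) - wmean(s) * wmean(t)) / vs
    c(alpha = wmean(t) - beta * wmean(s), beta = beta)
  }
  par <- fit2()
  if (par["beta"] < 0) par <- c(alpha = max(0, wmean(t)), beta = 0)
  if (par["alpha"] < 0) {
    beta <- wmean(s * t) / wmean(s^2)
    par <- c(alpha = 0, beta = max(0, beta))
  }
  sse <- sum(w * (t - par["alpha"] - par["beta"] * s)^2)
  list(alpha = unname(par["alpha"]), beta = unname(par["beta"]), sse = sse)
}

#' Variogram-matched surrogate maps
#'
#' Generates null maps preserving a target map's spatial autocorrelation:
#' each surrogate starts as a random permutation of the map's values, is
#' smoothed with the best Gaussian kernel from a candidate set, combined
#' with white noise so that its empirical variogram matches the target's by
#' least squares over distance bins (`target ~ beta * smoothed + alpha`),
#' and finally rescaled to the target's exact in-mask mean and SD. A
#' constant map yields constant surrogates.
#'
#' @param map Target [volume_map()] (>= 100 in-mask voxels).
#' @param n Number of surrogates.
#' @param seed Integer seed; the surrogate set is reproducible.
#' @param kernels_mm Candidate smoothing FWHMs in mm; defaults to a ladder
#'   from one to eight voxel widths.
#' @param n_bins,pairs_per_bin Variogram estimation parameters.
#' @return A list of class `surrogate_set`: `data` (n x in-mask-voxels
#'   matrix), `ref` (the target map), `kernel_mm` (chosen kernel per
#'   surrogate), `pairs` (the shared variogram pair sample).
#' @export
generate_surrogates <- function(map, n = 1000, seed = 1L, kernels_mm = NULL,
                                n_bins = 25, pairs_per_bin = 5000) {
  stopifnot(inherits(map, "volume_map"), n >= 1)
  x <- mask_values(map)
  n_in <- length(x)
  if (n_in < 100)
    stop("mask too small for variogram estimation (need >= 100 voxels)",
         call. = FALSE)
  vox <- abs(map$affine[1, 1])
  if (is.null(kernels_mm)) kernels_mm <- vox * c(0.75, 1.25, 1.6, 2, 2.5, 3, 4, 6, 8)

  if (stats::sd(x) == 0) {
    return(structure(list(data = matrix(rep(x, n), n, n_in, byrow = TRUE),
                          ref = map, kernel_mm = rep(0, n), pairs = NULL),
                     class = "surrogate_set"))
  }

  coords <- mask_coords_mm(map)
  pairs <- vario_pairs(coords, n_bins, pairs_per_bin, seed)
  g_target <- vario_of(x, pairs)$semivariance
  mask <- map$mask
  dims <- dim(map$values)
  sm_mask <- lapply(kernels_mm, function(fw) {
    s <- fwhm_to_sigma(fw, vox)
    gaussian_smooth_3d(mask * 1, rep(s, 3))
  })

  out <- matrix(0, n, n_in)
  kern <- numeric(n)
  withr::with_seed(seed + 1L, {
    for (b in seq_len(n)) {
      perm <- sample(x)
      vol <- array(0, dims)
      vol[mask] <- perm
      best <- NULL
      for (kk in seq_along(kernels_mm)) {
        s <- fwhm_to_sigma(kernels_mm[kk], vox)
        sm <- masked_smooth(vol, mask, rep(s, 3), den = sm_mask[[kk]])
        sv <- sm[mask]
        fit <- vario_match(g_target, vario_of(sv, pairs)$semivariance,
                           weights = pairs$n_per_bin)
        if (is.null(best) || fit$sse < best$fit$sse)
          best <- list(fit = fit, sv = sv, kernel = kernels_mm[kk])
      }
      surr <- sqrt(best$fit$beta) * (best$sv - mean(best$sv)) +
        sqrt(best$fit$alpha) * stats::rnorm(n_in)
      # exact first/second moment match to the target values
      if (stats::sd(surr) > 0) {
        surr <- (surr - mean(surr)) / stats::sd(surr) * stats::sd(x) + mean(x)
      } else {
        surr <- surr + mean(x)
      }
      out[b, ] <- surr
      kern[b] <- best$kernel
    }
  })
  structure(list(data = out, ref = map, kernel_mm = kern, pairs = pairs),
            class = "surrogate_set")
}

#' Extract one surrogate as a volume map
#'
#' @param ss A `surrogate_set`.
#' @param i Surrogate index.
#' @return A [volume_map()].
#' @export
surrogate_volume <- function(ss, i) {
  stopifnot(inherits(ss, "surrogate_set"))
  embed_values(ss$data[i, ], ss$ref, name = sprintf("surrogate%04d", i))
}

cos_vec <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

#' Similarity between two maps with an autocorrelation-preserving null
#'
#' Computes the observed cosine similarity between `a` and `b` and its
#' significance against variogram-matched surrogates of the comparison map
#' `b` (the reference map `a` stays fixed). The p-value is two-sided by
#' absolute value with the add-one convention:
#' `p = (#\{|null| >= |observed|\} + 1) / (n + 1)`. With an atlas, the same
#' test is run per network (no cross-network multiplicity correction by
#' default; set `adjust = "BH"` to correct).
#'
#' @param a Reference [volume_map()].
#' @param b Comparison [volume_map()] (surrogated).
#' @param atlas Optional integer-labelled [volume_map()].
#' @param n Number of surrogates.
#' @param seed Integer seed.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method applied
#'   across networks.
#' @param ... Passed to [generate_surrogates()] (e.g. `pairs_per_bin`).
#' @return A list of class `similarity_result_set`: `whole_brain` (list with
#'   `scope`, `observed`, `null_values`, `p`) and, with an atlas,
#'   `networks` (the same per label).
#' @export
similarity_pvalue <- function(a, b, atlas = NULL, n = 1000, seed = 1L,
                              adjust = "none", ...) {
  stop_if_misaligned(a, b)
  ss <- generate_surrogates(b, n = n, seed = seed, ...)
  joint <- a$mask & b$mask
  keep <- joint[b$mask]
  av <- a$values[joint]
  obs <- cos_vec(av, b$values[joint])
  nulls <- apply(ss$data[, keep, drop = FALSE], 1, cos_vec, x = av)
  res <- list(
    whole_brain = list(scope = "whole_brain", observed = obs,
                       null_values = nulls,
                       p = add_one_pvalue(nulls, obs, two_sided = TRUE))
  )
  if (!is.null(atlas)) {
    stop_if_misaligned(a, atlas, "map and atlas")
    labels <- sort(unique(atlas$values[atlas$mask & atlas$values != 0]))
    nets <- list()
    for (lb in labels) {
      sel <- (atlas$values == lb & atlas$mask)[b$mask] & keep
      avn <- a$values[b$mask][sel]
      bvn <- b$values[b$mask][sel]
      if (length(avn) < 2 || sum(avn^2) == 0 || sum(bvn^2) == 0) {
        nets[[as.character(lb)]] <- list(scope = paste0("network:", lb),
                                         observed = NA_real_,
                                         null_values = NULL, p = NA_real_)
        next
      }
      o <- cos_vec(avn, bvn)
      nv <- apply(ss$data[, sel, drop = FALSE], 1, cos_vec, x = avn)
      nets[[as.character(lb)]] <- list(
        scope = paste0("network:", lb), observed = o, null_values = nv,
        p = add_one_pvalue(nv, o, two_sided = TRUE))
    }
    if (adjust != "none") {
      ps <- vapply(nets, `[[`, numeric(1), "p")
      adj <- stats::p.adjust(ps, method = adjust)
      for (k in seq_along(nets)) nets[[k]]$p_adjusted <- adj[k]
    }
    res$networks <- nets
  }
  structure(res, class = "similarity_result_set")
}

#' @export
print.similarity_result_set <- function(x, ...) {
  wb <- x$whole_brain
  cat(sprintf("<similarity_result_set> whole-brain cosine = %.4f, p = %.4g\n",
              wb$observed, wb$p))
  if (!is.null(x$networks)) {
    for (nt in x$networks)
      cat(sprintf("  %s: cosine = %.4f, p = %.4g\n",
                  nt$scope, nt$observed, nt$p))
  }
  invisible(x)
}
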