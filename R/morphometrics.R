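# ---- band sampling and peak detection ---------------------------------------

# moving-average smoothing over a window of given arc width
smooth_profile <- function(s, w, width) {
  out <- numeric(length(w))
  for (i in seq_along(w)) {
    sel <- abs(s - s[i]) <= width / 2
    out[i] <- mean(w[sel])
  }
  out
}

# interior local maxima of y with their topographic prominence
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(idx = integer(0), prominence = numeric(0)))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[idx > 1 & idx < n]
  prom <- vapply(idx, function(i) {
    lefthi <- which(y[seq_len(i - 1)] > y[i])
    lo <- if (length(lefthi)) max(lefthi) + 1L else 1L
    leftbase <- min(y[lo:i])
    righthi <- which(y[(i + 1):n] > y[i]) + i
    hi <- if (length(righthi)) min(righthi) - 1L else n
    rightbase <- min(y[i:hi])
    y[i] - max(leftbase, rightbase)
  }, numeric(1))
  data.frame(idx = idx, prominence = prom)
}

# Extract the displacement profile of one sampling band: anterior-surface
# nodes on the lattice row closest to geodesic fraction `frac` from the fixed
# boundary, ordered along the band, with reference arc positions.
band_profile <- function(state, mesh, frac) {
  sp <- mesh$surface_param
  surf <- which(!is.na(sp[, 1]))
  vvals <- sort(unique(sp[surf, 2]))
  v0 <- vvals[which.min(abs(vvals - frac))]
  nodes <- surf[abs(sp[surf, 2] - v0) < 1e-12]
  nodes <- nodes[order(sp[nodes, 1])]
  ref <- mesh$nodes[nodes, , drop = FALSE]
  seg <- sqrt(rowSums((ref[-1, , drop = FALSE] -
                         ref[-nrow(ref), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  w <- state$x[nodes, 3] - ref[, 3]  # displacement along the reference normal
  list(nodes = nodes, s = s, w = w, v = v0)
}

#' Count ridges on the anterior surface
#'
#' The converged normal displacement is sampled along 5 concentric bands at
#' geodesic-distance fractions 0.2-0.8 from the fixed boundary, smoothed
#' over a window of `3 * spacing_a`, and local maxima with topographic
#' prominence of at least `prominence_frac` of the band's displacement range
#' are counted. Bands whose total displacement range is below
#' `amplitude_floor * T` are reported flat (0 ridges). The per-lobe ridge
#' count is the modal band count; ties resolve to the band nearest
#' mid-frill.
#'
#' @param state a converged `solver_state`.
#' @param mesh the `tet_mesh` the state belongs to.
#' @param bands geodesic-distance fractions of the sampling bands.
#' @param prominence_frac prominence threshold, as a fraction of the band
#'   displacement range.
#' @param amplitude_floor flatness threshold, as a fraction of the sheet
#'   thickness.
#' @param allow_unconverged accept an unconverged state (quasi-static
#'   intermediate inspection).
#' @return list with `ridge_count`, `band_counts`, `prominence_frac`, and
#'   `bands` (per-band profiles and peak indices).
#' @export
count_ridges <- function(state, mesh, bands = c(0.2, 0.35, 0.5, 0.65, 0.8),
                         prominence_frac = 0.1, amplitude_floor = 0.05,
                         allow_unconverged = FALSE) {
  stopifnot(inherits(state, "solver_state"))
  if (!allow_unconverged && !isTRUE(state$converged))
    stop("state is not converged; refusing to count ridges")
  floor_abs <- amplitude_floor * mesh$thickness_T
  out <- lapply(bands, function(f) {
    bp <- band_profile(state, mesh, f)
    ws <- smooth_profile(bp$s, bp$w, 3 * mesh$spacing_a)
    rng <- diff(range(ws))
    if (rng < floor_abs) {
      bp$count <- 0L
      bp$peaks <- integer(0)
    } else {
      pk <- find_peaks(ws)
      keep <- pk$prominence >= prominence_frac * rng
      bp$peaks <- pk$idx[keep]
      bp$count <- sum(keep)
    }
    bp$w_smooth <- ws
    bp
  })
  counts <- vapply(out, `[[`, integer(1), "count")
  tab <- table(counts)
  modal <- as.integer(names(tab)[tab == max(tab)])
  if (length(modal) > 1) {  # tie: band nearest mid-frill decides
    ord <- order(abs(bands - 0.5))
    modal <- counts[ord][counts[ord] %in% modal][1]
  }
  list(ridge_count = as.integer(modal), band_counts = counts,
       band_fracs = bands, prominence_frac = prominence_frac, bands = out)
}

#' Amplitude of the middle ridge
#'
#' Peak-to-adjacent-trough normal displacement of the ridge nearest the
#' middle of the mid-frill sampling band, in mm and as a percentage of the
#' fixed inner-boundary length L. Peaks and troughs are located on the
#' smoothed profile but the amplitude is read from the raw displacements.
#' Undefined (reported absent) for fewer than 2 ridges.
#'
#' @inheritParams count_ridges
#' @param ridges optional precomputed result of [count_ridges()].
#' @return list with `present`, `amplitude_mm`, `amplitude_pct_L`.
#' @export
middle_ridge_amplitude <- function(state, mesh, ridges = NULL,
                                   allow_unconverged = FALSE) {
  if (is.null(ridges))
    ridges <- count_ridges(state, mesh, allow_unconverged = allow_unconverged)
  if (ridges$ridge_count < 2)
    return(list(present = FALSE, amplitude_mm = NA_real_,
                amplitude_pct_L = NA_real_))
  mid <- ridges$bands[[which.min(abs(ridges$band_fracs - 0.5))]]
  if (length(mid$peaks) < 2) {
    cand <- ridges$bands[vapply(ridges$bands, function(b)
      length(b$peaks), integer(1)) >= 2]
    if (length(cand) == 0)
      return(list(present = FALSE, amplitude_mm = NA_real_,
                  amplitude_pct_L = NA_real_))
    mid <- cand[[1]]
  }
  smid <- max(mid$s) / 2
  pk <- mid$peaks[which.min(abs(mid$s[mid$peaks] - smid))]
  # adjacent troughs: raw minima between this peak and its neighbours (or edges)
  nbr <- sort(mid$peaks)
  left_lim <- max(c(1L, nbr[nbr < pk]))
  right_lim <- min(c(length(mid$w), nbr[nbr > pk]))
  trough_left <- min(mid$w[left_lim:pk])
  trough_right <- min(mid$w[pk:right_lim])
  amp <- mid$w[pk] - mean(c(trough_left, trough_right))
  list(present = TRUE, amplitude_mm = amp,
       amplitude_pct_L = 100 * amp / mesh$inner_boundary_length_L)
}

#' Analytic film-on-substrate wrinkling wavelength
#'
#' \deqn{\lambda = 2 \pi T \left(\frac{\mu_k}{3 \mu_s}\right)^{1/3}}
#' for a compressed stiff film of thickness `T` and shear modulus `mu_k` on
#' a soft half-space of shear modulus `mu_s`.
#'
#' @param T film thickness (mm).
#' @param mu_k film shear modulus.
#' @param mu_s substrate shear modulus.
#' @return wavelength (mm).
#' @export
analytic_wavelength <- function(T, mu_k, mu_s) {
  if (T <= 0 || mu_k <= 0 || mu_s <= 0) stop("all arguments must be positive")
  2 * pi * T * (mu_k / (3 * mu_s))^(1 / 3)
}

#' Measured wrinkle wavelength
#'
#' Mean of successive peak-to-peak arc distances on the mid-frill band (in
#' reference arc length); the standard deviation is taken across the
#' per-band mean wavelengths.
#'
#' @inheritParams middle_ridge_amplitude
#' @return list with `mean_mm`, `sd_mm`, `band_means` (per band, NA when a
#'   band has fewer than 2 peaks).
#' @export
measured_wavelength <- function(state, mesh, ridges = NULL,
                                allow_unconverged = FALSE) {
  if (is.null(ridges))
    ridges <- count_ridges(state, mesh, allow_unconverged = allow_unconverged)
  band_means <- vapply(ridges$bands, function(b) {
    if (length(b$peaks) < 2) return(NA_real_)
    mean(diff(b$s[sort(b$peaks)]))
  }, numeric(1))
  mid_i <- which.min(abs(ridges$band_fracs - 0.5))
  m <- band_means[mid_i]
  if (is.na(m)) m <- mean(band_means, na.rm = TRUE)
  list(mean_mm = m, sd_mm = stats::sd(band_means, na.rm = TRUE),
       band_means = band_means)
}

#' Realized linear surface growth
#'
#' Square root of the ratio of the deformed to the reference anterior
#' surface area. Because the neck boundary is held fixed, this matches the
#' boundary-relative linear growth measure used on embryos; elastic
#' compression makes it smaller than the applied growth factor.
#'
#' @inheritParams count_ridges
#' @return dimensionless linear growth factor.
#' @export
realized_linear_surface_growth <- function(state, mesh,
                                           allow_unconverged = FALSE) {
  stopifnot(inherits(state, "solver_state"))
  tri_area <- function(x, tris) {
    a <- x[tris[, 2], , drop = FALSE] - x[tris[, 1], , drop = FALSE]
    b <- x[tris[, 3], , drop = FALSE] - x[tris[, 1], , drop = FALSE]
    cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  }
  sqrt(tri_area(state$x, mesh$surface_tris) /
         tri_area(mesh$nodes, mesh$surface_tris))
}

#' Full morphometric report of a converged state
#'
#' @inheritParams count_ridges
#' @param prominence_frac prominence threshold passed to [count_ridges()].
#' @return an object of class `ridge_report`: ridge count, per-band counts,
#'   middle-ridge amplitude (mm and % of L), mean wavelength and its
#'   spread, and the realized linear surface growth.
#' @export
ridge_report <- function(state, mesh, prominence_frac = 0.1,
                         allow_unconverged = FALSE) {
  ridges <- count_ridges(state, mesh, prominence_frac = prominence_frac,
                         allow_unconverged = allow_unconverged)
  amp <- middle_ridge_amplitude(state, mesh, ridges)
  wl <- measured_wavelength(state, mesh, ridges)
  structure(list(
    ridge_count = ridges$ridge_count, band_counts = ridges$band_counts,
    prominence_frac = prominence_frac,
    middle_ridge_amplitude_mm = amp$amplitude_mm,
    middle_ridge_amplitude_pct_L = amp$amplitude_pct_L,
    mean_wavelength_mm = wl$mean_mm, sd_wavelength_mm = wl$sd_mm,
    band_wavelengths_mm = wl$band_means,
    realized_linear_growth = realized_linear_surface_growth(
      state, mesh, allow_unconverged = allow_unconverged),
    converged = isTRUE(state$converged)), class = "ridge_report")
}

#' @export
print.ridge_report <- function(x, ...) {
  cat("ridge report (prominence threshold ", x$prominence_frac * 100, "%):\n",
      sep = "")
  cat("  ridges per lobe:", x$ridge_count,
      "(bands:", paste(x$band_counts, collapse = ", "), ")\n")
  if (!is.na(x$middle_ridge_amplitude_mm))
    cat("  middle ridge amplitude:", signif(x$middle_ridge_amplitude_mm, 4),
        "mm (", signif(x$middle_ridge_amplitude_pct_L, 3), "% of L)\n")
  if (!is.na(x$mean_wavelength_mm))
    cat("  mean wavelength:", signif(x$mean_wavelength_mm, 4), "+/-",
        signif(x$sd_wavelength_mm, 3), "mm\n")
  cat("  realized linear surface growth:",
      signif(x$realized_linear_growth, 4), "\n")
  invisible(x)
}
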