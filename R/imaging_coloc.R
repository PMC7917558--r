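#' Otsu threshold of in-mask intensities
#'
#' Builds a 256-bin histogram of the masked pixels and returns the threshold
#' (a bin boundary) maximizing the between-class variance; exhaustive search
#' over all candidate boundaries, ties broken toward the lower threshold.
#' Pixels strictly above the threshold are foreground.
#'
#' @param img numeric intensity matrix.
#' @param mask logical matrix of the same shape (default: all pixels).
#' @param n_bins histogram resolution.
#' @return the threshold intensity.
#' @export
otsu_threshold <- function(img, mask = NULL, n_bins = 256L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("constant image within mask: Otsu threshold undefined",
         call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  mids <- (utils::head(breaks, -1L) + utils::tail(breaks, -1L)) / 2
  h <- tabulate(pmin(n_bins, findInterval(v, breaks, rightmost.closed = TRUE)),
                nbins = n_bins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[t_idx]
  valid <- w0[t_idx] > 0 & w1 > 0
  bc <- rep(-Inf, n_bins - 1L)
  bc[valid] <- (mu_t * w0[t_idx][valid] - mu[t_idx][valid])^2 /
    (w0[t_idx][valid] * w1[valid])
  best <- which.max(bc)  # ties: which.max returns the first = lower threshold
  breaks[best + 1L]
}

#' Segment foci as connected components above a threshold
#'
#' 8-connected components of above-threshold in-mask pixels, filtered by a
#' minimal area.
#'
#' @param img focus-channel intensity matrix.
#' @param mask logical nucleus mask.
#' @param min_area minimal component area in pixels.
#' @param threshold intensity threshold; [otsu_threshold()] of the masked
#'   image when `NULL`.
#' @return list of foci, each an integer vector of pixel indices into `img`;
#'   empty list when nothing is segmented.
#' @export
segment_foci <- function(img, mask = NULL, min_area = 4L, threshold = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  if (is.null(threshold)) threshold <- otsu_threshold(img, mask)
  fg <- img > threshold & mask
  lab <- label_components8(fg)
  if (max(lab) == 0L) return(list())
  comps <- split(which(lab > 0L), lab[lab > 0L])
  comps <- comps[vapply(comps, length, integer(1)) >= min_area]
  unname(comps)
}

# 8-connectivity flood fill on a logical matrix
label_components8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(fg)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L; c <- (q - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        p <- (cc - 1L) * nr + rr
        if (fg[p] && lab[p] == 0L) {
          lab[p] <- cur
          queue <- c(queue, p)
        }
      }
    }
  }
  lab
}

#' In-foci versus random-background enrichment of a measured channel
#'
#' Mean intensity of the measured channel over all foci pixels, divided by
#' the mean over `n_random` randomly placed disk ROIs (each matching the
#' mean focus area) inside the nucleus mask but outside the foci.
#'
#' @param measure_img measured-channel intensity matrix (e.g. GFP).
#' @param foci foci list from [segment_foci()]; must be non-empty.
#' @param mask logical nucleus mask.
#' @param n_random number of random background ROIs (>= 10 by convention).
#' @param seed RNG seed for the placements.
#' @param max_tries placement retries per ROI before failing.
#' @return object of class `foci_measurement`: list with `n_foci`,
#'   `in_foci_mean`, `background_mean`, `ratio`, `n_random`.
#' @export
coloc_ratio <- function(measure_img, foci, mask, n_random = 10L, seed = 1L,
                        max_tries = 2000L) {
  if (!length(foci)) stop("no foci to measure", call. = FALSE)
  set.seed(seed)
  nr <- nrow(measure_img); nc <- ncol(measure_img)
  foci_px <- unique(unlist(foci))
  mean_area <- mean(vapply(foci, length, integer(1)))
  radius <- max(1, sqrt(mean_area / pi))
  allowed <- mask
  allowed[foci_px] <- FALSE
  allowed_idx <- which(allowed)
  if (length(allowed_idx) < n_random * mean_area)
    stop("mask too small for ", n_random, " background placements",
         call. = FALSE)
  ro <- as.integer(round(radius))
  offs <- expand.grid(dr = -ro:ro, dc = -ro:ro)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  bg_means <- numeric(n_random)
  for (i in seq_len(n_random)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- allowed_idx[sample.int(length(allowed_idx), 1L)]
      r <- (ctr - 1L) %% nr + 1L; c <- (ctr - 1L) %/% nr + 1L
      rr <- r + offs$dr; cc <- c + offs$dc
      if (any(rr < 1L | rr > nr | cc < 1L | cc > nc)) next
      px <- (cc - 1L) * nr + rr
      if (!all(allowed[px])) next
      bg_means[i] <- mean(measure_img[px])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place background ROI ", i, " after ", max_tries,
           " attempts", call. = FALSE)
  }
  bg <- mean(bg_means)
  if (bg <= 0) stop("background mean must be positive", call. = FALSE)
  infoci <- mean(measure_img[foci_px])
  structure(list(n_foci = length(foci), in_foci_mean = infoci,
                 background_mean = bg, ratio = infoci / bg,
                 n_random = n_random),
            class = "foci_measurement")
}

#' @export
print.foci_measurement <- function(x, ...) {
  cat("foci_measurement: ", x$n_foci, " foci, in-foci/background ratio ",
      round(x$ratio, 3), " (", x$n_random, " random ROIs)\n", sep = "")
  invisible(x)
}

#' Welch's t-test on per-nucleus enrichment ratios
#'
#' @param ratios_a,ratios_b numeric vectors of per-nucleus ratios (>= 2
#'   each).
#' @return list with `p_value`, `statistic`, `mean_a`, `mean_b`.
#' @export
genotype_test <- function(ratios_a, ratios_b) {
  if (length(ratios_a) < 2L || length(ratios_b) < 2L)
    stop("at least 2 nuclei per group are required", call. = FALSE)
  if (sd(ratios_a) == 0 && sd(ratios_b) == 0 &&
      mean(ratios_a) == mean(ratios_b))
    return(list(p_value = 1, statistic = 0,
                mean_a = mean(ratios_a), mean_b = mean(ratios_b)))
  tt <- t.test(ratios_a, ratios_b)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       mean_a = mean(ratios_a), mean_b = mean(ratios_b))
}

#' End-to-end colocalization quantification of simulated image pairs
#'
#' Segments mCherry foci by Otsu within the nucleus mask and measures the
#' GFP in-foci/background ratio per nucleus.
#'
#' @param images output of [make_images()].
#' @param n_random random background ROIs per nucleus.
#' @param min_area minimal focus area (pixels).
#' @param seed RNG seed for background placements.
#' @return numeric vector of per-nucleus ratios.
#' @export
coloc_pipeline <- function(images, n_random = 10L, min_area = 4L, seed = 1L) {
  vapply(seq_along(images), function(i) {
    im <- images[[i]]
    foci <- segment_foci(im$mcherry, im$mask, min_area = min_area)
    coloc_ratio(im$gfp, foci, im$mask, n_random = n_random,
                seed = seed + i)$ratio
  }, numeric(1))
}
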