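#' Simulate two-channel nuclear images
#'
#' Each nucleus is a disk-shaped mask inscribed in the image. The mCherry
#' (focus) channel carries `cfg$n_foci` Gaussian spots inside the nucleus on
#' a flat background; the GFP (measured) channel is a uniform nuclear
#' baseline that, when `colocalized`, is multiplied by `cfg$foci_enrichment`
#' over a disk covering each spot. Optional Poisson shot noise is applied
#' per pixel.
#'
#' @param cfg a [syn_config()] object.
#' @param colocalized logical; whether the GFP channel is enriched at the
#'   mCherry foci.
#' @param n_nuclei number of nuclei (image pairs) to generate.
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return a list of length `n_nuclei`; each element has matrices `mcherry`,
#'   `gfp` (intensities, photon-count scale) and logical `mask`.
#' @export
make_images <- function(cfg, colocalized = TRUE, n_nuclei = 1L, seed = NULL) {
  if (cfg$n_foci < 1L) stop("n_foci must be >= 1", call. = FALSE)
  set.seed(stage_seed(if (is.null(seed)) cfg$seed else seed, "images",
                      if (colocalized) "coloc" else "nocoloc"))
  n <- cfg$image_size
  ctr <- (n + 1) / 2
  R <- 0.45 * n
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  d2 <- (xy$x - ctr)^2 + (xy$y - ctr)^2
  mask <- matrix(d2 <= R^2, n, n)

  sigma <- 2
  spot_r <- 3 * sigma          # GFP enrichment disk covers the segmented spot
  baseline_mch <- 100; amp_mch <- 800; baseline_gfp <- 200

  lapply(seq_len(n_nuclei), function(k) {
    centers <- matrix(NA_real_, cfg$n_foci, 2L)
    for (f in seq_len(cfg$n_foci)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- ctr + (R - spot_r - 2) * runif(2, -1, 1)
        if (sum((cand - ctr)^2) > (R - spot_r - 2)^2) next
        if (f > 1L && any(sqrt(rowSums(
          (centers[seq_len(f - 1L), , drop = FALSE] -
             matrix(cand, f - 1L, 2L, byrow = TRUE))^2)) < 6 * sigma)) next
        centers[f, ] <- cand; ok <- TRUE; break
      }
      if (!ok) stop("could not place focus ", f,
                    " inside the nucleus after bounded retries",
                    call. = FALSE)
    }
    mch <- matrix(baseline_mch, n, n)
    gfp <- matrix(baseline_gfp, n, n)
    for (f in seq_len(cfg$n_foci)) {
      dd2 <- (xy$x - centers[f, 1])^2 + (xy$y - centers[f, 2])^2
      mch <- mch + matrix(amp_mch * exp(-dd2 / (2 * sigma^2)), n, n)
      if (colocalized)
        gfp[matrix(dd2 <= spot_r^2, n, n)] <-
          baseline_gfp * cfg$foci_enrichment
    }
    mch[!mask] <- 0; gfp[!mask] <- 0
    if (cfg$image_noise == "poisson") {
      mch[] <- rpois(length(mch), mch)
      gfp[] <- rpois(length(gfp), gfp)
    }
    list(mcherry = mch, gfp = gfp, mask = mask)
  })
}
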