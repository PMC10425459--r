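#' Chromatin and cytoplasm masks from a DNA channel
#'
#' The chromatin region of interest is the part of the cell where the
#' DNA-channel intensity reaches a threshold; the cytoplasm ROI is the
#' rest of the cell mask. The threshold is either a fixed value or
#' Otsu's method computed on the DNA intensities inside the cell mask.
#' Automatic thresholding approximates the manual ROI delineation used
#' in microscopy practice and is flagged as such in the result.
#'
#' @param dna Numeric matrix, DNA-channel intensities.
#' @param cell_mask Logical matrix of the same shape: the whole-cell
#'   region.
#' @param threshold Either `"otsu"` or a fixed numeric threshold.
#' @return A list with logical matrices `chromatin` and `cytoplasm`
#'   (a partition of `cell_mask`), the `threshold` used, and flags
#'   `chromatin_empty` / `cytoplasm_empty`.
#' @export
make_masks <- function(dna, cell_mask, threshold = "otsu") {
  stopifnot(is.matrix(dna), identical(dim(dna), dim(cell_mask)))
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) stop("empty cell mask")
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(dna[cell_mask])
  } else {
    as.numeric(threshold)
  }
  chromatin <- (dna >= thr) & cell_mask
  cytoplasm <- cell_mask & !chromatin
  list(chromatin = chromatin, cytoplasm = cytoplasm, threshold = thr,
       method = if (identical(threshold, "otsu")) "otsu" else "fixed",
       chromatin_empty = !any(chromatin),
       cytoplasm_empty = !any(cytoplasm))
}

#' Otsu threshold of an intensity sample
#'
#' Maximises the between-class variance over a 256-level histogram of
#' the input range; returns a threshold on the original intensity
#' scale.
#'
#' @param x Numeric vector of intensities.
#' @param levels Number of histogram levels (default 256).
#' @return Numeric threshold.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- graphics::hist(x, breaks = br, plot = FALSE)$counts
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # the variance curve is flat across an empty valley; take the
  # midpoint of the maximal plateau rather than its left edge
  peak_idx <- which(sigma_b >= max(sigma_b) - 1e-12 * max(sigma_b))
  br[round(mean(range(peak_idx))) + 1L]
}

#' Chromatin/cytoplasm retention ratio for one cell
#'
#' Mean intensity of the transcription-factor channel over the chromatin
#' ROI divided by the mean over the cytoplasm ROI, plus its log2. A
#' cytoplasm mean of 0 makes the ratio undefined; it is reported as
#' `NA`, never infinite.
#'
#' @param intensity Numeric matrix, TF-channel intensities.
#' @param chromatin,cytoplasm Logical masks (see [make_masks()]).
#' @param cell_id Identifier carried into the result.
#' @return A one-row `data.frame`: `cell_id`, `chromatin_mean`,
#'   `cytoplasm_mean`, `ratio`, `log2_ratio`.
#' @export
retention_ratio <- function(intensity, chromatin, cytoplasm,
                            cell_id = "cell") {
  stopifnot(is.matrix(intensity),
            identical(dim(intensity), dim(chromatin)),
            identical(dim(intensity), dim(cytoplasm)))
  if (!any(chromatin) || !any(cytoplasm)) {
    stop("both chromatin and cytoplasm masks must be non-empty")
  }
  chr_mean <- mean(intensity[chromatin > 0])
  cyt_mean <- mean(intensity[cytoplasm > 0])
  ratio <- if (cyt_mean > 0) chr_mean / cyt_mean else NA_real_
  data.frame(cell_id = cell_id,
             chromatin_mean = chr_mean,
             cytoplasm_mean = cyt_mean,
             ratio = ratio,
             log2_ratio = log2(ratio),
             stringsAsFactors = FALSE)
}

#' Compare retention between conditions
#'
#' One-way ANOVA on per-cell log2 chromatin/cytoplasm ratios across
#' conditions, followed by pairwise Welch t-tests with Bonferroni
#' correction, plus per-group mean and SD.
#'
#' @param measurements Named list of numeric vectors of log2 ratios, one
#'   per condition; at least 2 groups with at least 2 cells each.
#' @return A list: `anova` (F statistic, df, p), `pairwise`
#'   (`data.frame` with raw and Bonferroni-adjusted p per pair),
#'   `summary` (per-group n, mean, sd).
#' @export
compare_groups <- function(measurements) {
  if (length(measurements) < 2L) stop("need at least 2 groups")
  if (any(vapply(measurements, length, 1L) < 2L)) {
    stop("each group needs at least 2 cells")
  }
  if (is.null(names(measurements))) {
    names(measurements) <- paste0("group", seq_along(measurements))
  }
  df <- data.frame(
    value = unlist(measurements, use.names = FALSE),
    group = factor(rep(names(measurements),
                       vapply(measurements, length, 1L)))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(names(measurements), 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- measurements[[pw$group1[i]]]
    b <- measurements[[pw$group2[i]]]
    pw$p_raw[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                       mean(a) == mean(b)) {
      1
    } else {
      stats::t.test(a, b)$p.value
    }
  }
  pw$p_adjusted <- pmin(pw$p_raw * m, 1)
  list(
    anova = list(F = an$`F value`[1], df = unname(an$Df),
                 p_value = an$`Pr(>F)`[1]),
    pairwise = pw,
    summary = data.frame(
      group = names(measurements),
      n = vapply(measurements, length, 1L),
      mean = vapply(measurements, mean, numeric(1)),
      sd = vapply(measurements, stats::sd, numeric(1)),
      stringsAsFactors = FALSE
    )
  )
}
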