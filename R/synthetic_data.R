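# Synthetic genotype/phenotype simulation.
#
# Generates biallelic SNP dosage matrices under Hardy-Weinberg sampling and
# single-trait phenotypes with an additive genetic architecture, so every
# downstream stage (GRM, GBLUP, calibration, outlier filtering, evaluation)
# can be exercised without external data.

#' Marker-count ceiling applied by [dataset_profile()]
#'
#' Profiles emulating large real genotyping panels are capped at this many
#' markers: GRM-based prediction accuracy saturates well below it, and it
#' keeps simulated runs tractable on a single CPU.
#'
#' @export
MARKER_CAP <- 5000L

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#'
#' @param n_lines Number of lines (individuals). Positive integer.
#' @param n_markers Number of biallelic SNP markers. Positive integer.
#' @param maf_range Length-2 numeric, ordered minor-allele-frequency bounds in
#'   (0, 0.5]; each marker's allele frequency is drawn uniformly between them.
#' @param n_qtl Number of causal markers (<= `n_markers`).
#' @param heritability Narrow-sense heritability of the simulated trait,
#'   strictly between 0 and 1.
#' @param trait_mean,trait_sd Location and scale of the phenotype
#'   (`trait_sd` > 0).
#' @param skew Skewness coefficient of the residual distribution; 0 gives
#'   Gaussian residuals, otherwise a standardized shifted-gamma is used.
#' @param outlier_fraction Fraction of lines contaminated by a location
#'   shift, in [0, 0.5).
#' @param outlier_magnitude Size of the contamination shift in residual-SD
#'   units (> 0).
#' @param seed Integer seed; all generator output is deterministic given it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_lines = 100, n_markers = 500, seed = 1)
#' @export
sim_config <- function(n_lines,
                       n_markers,
                       maf_range = c(0.05, 0.5),
                       n_qtl = min(300L, n_markers),
                       heritability = 0.5,
                       trait_mean = 10,
                       trait_sd = 1,
                       skew = 0,
                       outlier_fraction = 0,
                       outlier_magnitude = 5,
                       seed = 1L) {
  n_lines <- as.integer(n_lines)
  n_markers <- as.integer(n_markers)
  n_qtl <- as.integer(n_qtl)
  if (is.na(n_lines) || n_lines < 1L || is.na(n_markers) || n_markers < 1L) {
    stop("`n_lines` and `n_markers` must be positive integers", call. = FALSE)
  }
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("`maf_range` must be ordered bounds within (0, 0.5]", call. = FALSE)
  }
  if (is.na(n_qtl) || n_qtl < 1L || n_qtl > n_markers) {
    stop("`n_qtl` must be a positive integer <= n_markers", call. = FALSE)
  }
  if (!is.numeric(heritability) || length(heritability) != 1L ||
      is.na(heritability) || heritability <= 0 || heritability >= 1) {
    stop("`heritability` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(trait_sd) || trait_sd <= 0) {
    stop("`trait_sd` must be positive", call. = FALSE)
  }
  if (!is.numeric(outlier_fraction) || outlier_fraction < 0 ||
      outlier_fraction >= 0.5) {
    stop("`outlier_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(outlier_magnitude) || outlier_magnitude <= 0) {
    stop("`outlier_magnitude` must be positive", call. = FALSE)
  }
  structure(
    list(n_lines = n_lines, n_markers = n_markers,
         maf_range = as.numeric(maf_range), n_qtl = n_qtl,
         heritability = heritability, trait_mean = trait_mean,
         trait_sd = trait_sd, skew = skew,
         outlier_fraction = outlier_fraction,
         outlier_magnitude = outlier_magnitude,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a biallelic SNP dosage matrix
#'
#' Each marker j gets an allele frequency p_j drawn uniformly from
#' `maf_range`; dosages are Binomial(2, p_j) draws per line (Hardy-Weinberg
#' sampling). Output is bit-identical for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Integer matrix (lines x markers) with entries in \{0, 1, 2\},
#'   line IDs as rownames and marker IDs as colnames.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  m <- config$n_markers
  X <- with_seed(config$seed, {
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    matrix(stats::rbinom(n * m, size = 2L, prob = rep(p, each = n)),
           nrow = n, ncol = m)
  })
  dimnames(X) <- list(sprintf("L%04d", seq_len(n)),
                      sprintf("M%05d", seq_len(m)))
  X
}

#' Simulate phenotypes with an additive genetic architecture
#'
#' Draws `n_qtl` marker effects, forms genetic values as the centered-dosage
#' linear combination rescaled so that var(g) / (var(g) + sigma^2) equals the
#' requested heritability, adds residuals with variance sigma^2 (Gaussian, or
#' standardized shifted-gamma when `skew != 0`), and finally contaminates a
#' fraction of lines with an additive shift of +/- `outlier_magnitude` residual
#' SDs (random sign), recorded in `true_outlier_flags`.
#'
#' @param markers Dosage matrix from [simulate_genotypes()] (or compatible).
#' @param config The same [sim_config()].
#' @return An object of class `synthetic_dataset`: a list with `markers`,
#'   `phenotypes`, `true_genetic_values`, `true_outlier_flags` (all indexed by
#'   the marker rownames) and `config`.
#' @export
simulate_phenotypes <- function(markers, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(markers))
  n <- nrow(markers)
  ids <- rownames(markers)
  h2 <- config$heritability
  sigma_g <- sqrt(h2) * config$trait_sd
  sigma_e <- sqrt(1 - h2) * config$trait_sd

  out <- with_seed(config$seed + 1L, {
    qtl <- sample.int(ncol(markers), config$n_qtl)
    beta <- stats::rnorm(config$n_qtl)
    W <- scale(markers[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
    g_raw <- drop(W %*% beta)
    sg <- stats::sd(g_raw)
    if (sg < .Machine$double.eps) {
      stop("simulated genetic values are constant; increase n_qtl or MAF",
           call. = FALSE)
    }
    g <- g_raw / sg * sigma_g

    e <- if (config$skew == 0) {
      stats::rnorm(n, 0, sigma_e)
    } else {
      # Shifted gamma standardized to mean 0, variance sigma_e^2; the shape is
      # chosen so the skewness coefficient equals `skew` (gamma skewness is
      # 2/sqrt(shape)); negative skew mirrors the draw.
      shape <- (2 / abs(config$skew))^2
      raw <- stats::rgamma(n, shape = shape, scale = 1)
      z <- (raw - shape) / sqrt(shape)
      sign(config$skew) * z * sigma_e
    }

    y <- config$trait_mean + g + e
    flags <- rep(FALSE, n)
    n_out <- round(config$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      shift <- sample(c(-1, 1), n_out, replace = TRUE) *
        config$outlier_magnitude * sigma_e
      y[idx] <- y[idx] + shift
      flags[idx] <- TRUE
    }
    list(g = g, y = y, flags = flags)
  })

  structure(
    list(markers = markers,
         phenotypes = stats::setNames(out$y, ids),
         true_genetic_values = stats::setNames(out$g, ids),
         true_outlier_flags = stats::setNames(out$flags, ids),
         config = config),
    class = "synthetic_dataset"
  )
}

#' Simulate a complete dataset in one call
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset` (see [simulate_phenotypes()]).
#' @export
simulate_dataset <- function(config) {
  simulate_phenotypes(simulate_genotypes(config), config)
}

# Line and marker counts of the 14 benchmark datasets the generator emulates.
PROFILE_SHAPES <- data.frame(
  name = c("Indica", "Japonica", "Groundnut", "Maize",
           "Wheat_1", "Wheat_2", "Wheat_3", "Wheat_4", "Wheat_5", "Wheat_6",
           "EYT_1", "EYT_2", "EYT_3", "Disease"),
  n_lines = c(327L, 320L, 318L, 722L,
              1301L, 1403L, 1403L, 1388L, 1398L, 1277L,
              776L, 775L, 964L, 438L),
  n_markers = c(16383L, 16383L, 8268L, 54113L,
                78606L, 78606L, 78606L, 78606L, 78606L, 78606L,
                2038L, 2038L, 2038L, 11617L),
  stringsAsFactors = FALSE
)

#' Scaled simulation profile for a named benchmark dataset
#'
#' Returns a [sim_config()] whose line count matches the named dataset and
#' whose marker count is the real panel size capped at [MARKER_CAP]. The
#' trait parameters are neutral stand-ins (heritability 0.5, no skew, no
#' contamination): the real traits' distributions are not characterized, so
#' profiles fix only the shapes.
#'
#' @param name One of the 14 dataset names (e.g. `"Indica"`, `"EYT_1"`,
#'   `"Wheat_1"`).
#' @param ... Overrides passed on to [sim_config()] (e.g. `seed`,
#'   `heritability`).
#' @return A `sim_config`.
#' @examples
#' dataset_profile("EYT_1", seed = 7)
#' @export
dataset_profile <- function(name, ...) {
  i <- match(name, PROFILE_SHAPES$name)
  if (is.na(i)) {
    stop(sprintf("unknown dataset profile '%s'; available: %s", name,
                 paste(PROFILE_SHAPES$name, collapse = ", ")), call. = FALSE)
  }
  args <- list(n_lines = PROFILE_SHAPES$n_lines[i],
               n_markers = min(PROFILE_SHAPES$n_markers[i], MARKER_CAP))
  dots <- list(...)
  do.call(sim_config, c(args, dots))
}
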