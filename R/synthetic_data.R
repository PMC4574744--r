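#' Configuration for the synthetic expression generator
#'
#' Describes a positive-valued, MAS5-like expression matrix whose class
#' labels are governed by a small set of planted log-ratios. Sensitive
#' samples shift the numerator gene up and the denominator gene down (in
#' log space) so that the class-conditional mean log-ratio differs by
#' `effect_size * noise_sd`, while per-sample multiplicative scale factors
#' make absolute expression levels uninformative. Defaults mirror the
#' method's study conditions: 23% prevalence, linear-scale baseline 150.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total genes in the matrix.
#' @param hypothesis_set_size Size of the candidate gene list (first genes
#'   of the matrix).
#' @param n_true_ratios Number of planted ratios (disjoint gene pairs drawn
#'   from the hypothesis set).
#' @param effect_size Class difference in mean log-ratio, in units of
#'   `noise_sd`.
#' @param prevalence Fraction sensitive (default 0.23).
#' @param noise_sd Log-scale biological/technical noise SD.
#' @param pair_coupling_sd Log-scale SD of the shared per-pair latent
#'   factor: both genes of a planted pair move together with it
#'   (co-regulation), so the planted log-ratio cancels it while ratios
#'   pairing a planted gene with an unrelated gene inherit it as extra
#'   variance — this is what makes the planted pair, and not its
#'   one-gene-shared neighbours, the identifiable feature.
#' @param baseline Linear-scale platform floor (default 150); gene mean
#'   intensities are drawn log-normally at multiples of this floor.
#' @param per_sample_scale_range Range of per-sample multiplicative scale
#'   factors (log-uniform), emulating platform/batch effects.
#' @param per_gene_shift_sd Log-normal SD of per-gene platform shifts used
#'   by [generate_platform_replica()].
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 400, n_genes = 300,
                             hypothesis_set_size = 60, n_true_ratios = 5,
                             effect_size = 2, prevalence = 0.23,
                             noise_sd = 0.5, pair_coupling_sd = 3,
                             baseline = 150,
                             per_sample_scale_range = c(0.5, 2),
                             per_gene_shift_sd = 0.1, seed = 1) {
  stopifnot(n_samples > 0, n_genes > 0, hypothesis_set_size > 0,
            hypothesis_set_size <= n_genes, n_true_ratios >= 0,
            prevalence > 0, prevalence < 1, noise_sd > 0, baseline > 0,
            pair_coupling_sd >= 0,
            length(per_sample_scale_range) == 2,
            all(per_sample_scale_range > 0),
            per_gene_shift_sd >= 0)
  if (2 * n_true_ratios > hypothesis_set_size) {
    stop("n_true_ratios exceeds the available disjoint pairs")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic expression matrix with planted ratio structure
#'
#' Expression is log-normal around gene-specific mean intensities (drawn
#' log-normally at multiples of the platform baseline; hypothesis genes at
#' higher intensity so they survive the expression filters, as curated
#' pathway genes typically do). Labels are drawn at the configured
#' prevalence; each planted ratio separates the classes by
#' `effect_size * noise_sd` in mean log-ratio. Per-sample multiplicative
#' scale factors are applied uniformly to all genes of a sample.
#'
#' @param cfg A [synthetic_config()].
#' @return List: `X` (genes x samples matrix), `labels`
#'   (`"sensitive"`/`"insensitive"`), `truth` (data frame of planted
#'   `gene_num`, `gene_den`), `hypothesis_genes`, `config`.
#' @export
generate_expression <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    samples <- sprintf("S%04d", seq_len(cfg$n_samples))
    hyp <- genes[seq_len(cfg$hypothesis_set_size)]
    y <- runif(cfg$n_samples) < cfg$prevalence
    # planted pairs: disjoint genes from the hypothesis set
    planted_genes <- sample(hyp, 2 * cfg$n_true_ratios)
    truth <- if (cfg$n_true_ratios > 0) {
      data.frame(
        gene_num = planted_genes[seq_len(cfg$n_true_ratios)],
        gene_den = planted_genes[cfg$n_true_ratios + seq_len(cfg$n_true_ratios)],
        stringsAsFactors = FALSE)
    } else {
      data.frame(gene_num = character(0), gene_den = character(0))
    }
    # gene mean intensities (linear scale): log-normal multiples of baseline
    mu <- log(cfg$baseline) + rnorm(cfg$n_genes, mean = 2.0, sd = 0.9)
    names(mu) <- genes
    mu[hyp] <- log(cfg$baseline) + rnorm(length(hyp), mean = 2.5, sd = 0.3)
    # log-scale effects: numerator up / denominator down in sensitives,
    # plus a shared per-pair co-regulation factor that the planted ratio
    # cancels (both genes move together with it)
    shift <- cfg$effect_size * cfg$noise_sd / 2
    E <- matrix(0, cfg$n_genes, cfg$n_samples, dimnames = list(genes, samples))
    if (cfg$n_true_ratios > 0) {
      E[truth$gene_num, y] <- E[truth$gene_num, y] + shift
      E[truth$gene_den, y] <- E[truth$gene_den, y] - shift
      if (cfg$pair_coupling_sd > 0) {
        for (i in seq_len(cfg$n_true_ratios)) {
          u <- rnorm(cfg$n_samples, sd = cfg$pair_coupling_sd)
          E[truth$gene_num[i], ] <- E[truth$gene_num[i], ] + u
          E[truth$gene_den[i], ] <- E[truth$gene_den[i], ] + u
        }
      }
    }
    noise <- matrix(rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
                    cfg$n_genes, cfg$n_samples)
    lo <- log(cfg$per_sample_scale_range[1])
    hi <- log(cfg$per_sample_scale_range[2])
    alpha <- runif(cfg$n_samples, lo, hi)  # log per-sample scale
    X <- exp(mu + E + noise + rep(alpha, each = cfg$n_genes))
    dimnames(X) <- list(genes, samples)
    list(X = X, labels = ifelse(y, "sensitive", "insensitive"),
         truth = truth, hypothesis_genes = hyp, config = cfg)
  })
}

#' Platform-shifted replica of an expression matrix
#'
#' Emulates re-measuring the same samples on another platform:
#' `X'[g,s] = X[g,s] * alpha_s * beta_g` with per-sample factors `alpha`
#' log-uniform over `per_sample_scale_range` and per-gene factors `beta`
#' log-normal with SD `per_gene_shift_sd`. Used to test that ratio-based
#' predictions transfer without rescaling.
#'
#' @param X Positive expression matrix.
#' @param per_sample_scale_range Range (min, max) of per-sample factors.
#' @param per_gene_shift_sd Log-normal SD of per-gene factors.
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
generate_platform_replica <- function(X, per_sample_scale_range = c(0.5, 2),
                                      per_gene_shift_sd = 0.1, seed = 1) {
  validate_expression_matrix(X)
  stopifnot(all(per_sample_scale_range > 0), per_gene_shift_sd >= 0)
  withr::with_seed(seed, {
    alpha <- exp(runif(ncol(X), log(per_sample_scale_range[1]),
                       log(per_sample_scale_range[2])))
    beta <- exp(rnorm(nrow(X), sd = per_gene_shift_sd))
    X * outer(beta, alpha)
  })
}

#' Default 11-point dose grid
#'
#' 2.5-fold dilutions from 20 nM down (11 concentrations, molar),
#' ascending.
#'
#' @return Numeric vector of 11 doses.
#' @export
default_dose_grid <- function() {
  sort(20e-9 / 2.5^(0:10))
}

#' Generate multi-screen dose-response curves consistent with labels
#'
#' For each cell line and screen, draws a sigmoidal inhibition curve whose
#' plateau (Amax) falls in the band of its label — sensitive: 75-95%,
#' intermediate: 55-65%, insensitive: 15-45% — except that with probability
#' `concordance_noise` the call band is flipped to a different class,
#' emulating inter-screen discordance. Screen coverage can be thinned at
#' random.
#'
#' @param labels Named character vector of true calls per cell line
#'   (`"sensitive"`/`"intermediate"`/`"insensitive"`); names are the cell
#'   line ids (generated if absent).
#' @param n_screens Number of screens (default 3).
#' @param concordance_noise Per-measurement probability of a flipped call
#'   band.
#' @param dose_grid Ascending dose grid (default [default_dose_grid()]).
#' @param missing_rate Probability a line is missing from a screen (lines
#'   are kept in at least one screen).
#' @param curve_noise_sd SD of additive measurement noise on the curve
#'   points (% inhibition; default 0).
#' @param seed Integer seed.
#' @return Long data frame: `cell_line_id`, `screen_id`, `dose`,
#'   `inhibition`, `replicate`, plus attribute `"true_amax"` (per
#'   line/screen drawn plateau table).
#' @export
generate_screens <- function(labels, n_screens = 3, concordance_noise = 0,
                             dose_grid = default_dose_grid(),
                             missing_rate = 0, curve_noise_sd = 0, seed = 1) {
  stopifnot(is.character(labels), length(labels) > 0,
            !is.unsorted(dose_grid), all(dose_grid > 0),
            concordance_noise >= 0, concordance_noise <= 1,
            missing_rate >= 0, missing_rate < 1, curve_noise_sd >= 0)
  if (is.null(names(labels))) {
    names(labels) <- sprintf("CL%04d", seq_along(labels))
  }
  classes <- c("sensitive", "intermediate", "insensitive")
  stopifnot(all(labels %in% classes))
  bands <- list(sensitive = c(75, 95), intermediate = c(55, 65),
                insensitive = c(15, 45))
  withr::with_seed(seed, {
    rows <- list()
    amax_rows <- list()
    for (id in names(labels)) {
      present <- runif(n_screens) >= missing_rate
      if (!any(present)) present[sample.int(n_screens, 1)] <- TRUE
      for (s in which(present)) {
        cls <- labels[[id]]
        if (runif(1) < concordance_noise) {
          cls <- sample(setdiff(classes, cls), 1)
        }
        band <- bands[[cls]]
        amax <- runif(1, band[1], band[2])
        # inflection dose inside the central part of the grid
        ec50 <- exp(runif(1, log(dose_grid[3]),
                          log(dose_grid[length(dose_grid) - 2])))
        hill <- runif(1, 0.8, 1.5)
        inh <- amax / (1 + (ec50 / dose_grid)^hill)
        if (curve_noise_sd > 0) {
          inh <- inh + rnorm(length(inh), sd = curve_noise_sd)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line_id = id, screen_id = sprintf("screen%d", s),
          dose = dose_grid, inhibition = inh, replicate = 1L,
          stringsAsFactors = FALSE)
        amax_rows[[length(amax_rows) + 1L]] <- data.frame(
          cell_line_id = id, screen_id = sprintf("screen%d", s),
          true_amax = amax, drawn_class = cls, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "true_amax") <- do.call(rbind, amax_rows)
    out
  })
}
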