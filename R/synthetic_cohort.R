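#' Specify a synthetic pediatric-glioma cohort
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The generator plants two latent expression subtypes (I and II): HOX genes
#' and a set of additional differentially expressed (DE) genes are elevated
#' in subtype II, overall survival follows an exponential model with a
#' subtype-II hazard ratio, and per-sample total mutation counts are Poisson
#' with subtype-specific means. Batch structure is additive per gene.
#'
#' Defaults describe the cohort structure the downstream analysis assumes:
#' two subtypes at roughly 70/30 prevalence, a 2 log2-unit HOX elevation in
#' the poor-prognosis subtype, about 1000 planted DE genes, a subtype hazard
#' ratio of 2, and roughly 60% censoring.
#'
#' @param n_samples number of samples.
#' @param n_genes total number of genes (HOX + planted DE + null).
#' @param hox_gene_names identifiers of the HOX feature genes; defaults to
#'   the packaged 39-gene list.
#' @param subtype2_fraction probability a sample belongs to subtype II.
#' @param hox_shift mean log2-expression elevation of HOX genes in subtype II.
#' @param n_de_genes number of additional planted DE genes.
#' @param de_shift their log2 shift in subtype II.
#' @param noise_sd per-gene Gaussian noise SD (log2 units).
#' @param n_batches number of batches.
#' @param batch_shift_sd SD of per-batch, per-gene additive offsets.
#' @param baseline_median_survival median overall survival (months) of
#'   subtype I under the exponential model.
#' @param subtype_hr hazard ratio of subtype II versus subtype I.
#' @param censoring_rate target fraction of censored samples, achieved by
#'   independent uniform censoring.
#' @param mutation_rate_by_subtype length-2 positive means of the per-sample
#'   total mutation count (subtype I, subtype II).
#' @param seed RNG seed; the cohort is a deterministic function of the spec.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_samples = 300L,
                        n_genes = 2000L,
                        hox_gene_names = hox_gene_list(),
                        subtype2_fraction = 0.3,
                        hox_shift = 2,
                        n_de_genes = 1000L,
                        de_shift = 2,
                        noise_sd = 1,
                        n_batches = 2L,
                        batch_shift_sd = 0.5,
                        baseline_median_survival = 60,
                        subtype_hr = 2,
                        censoring_rate = 0.6,
                        mutation_rate_by_subtype = c(20, 60),
                        seed = 1L) {
  spec <- list(
    n_samples = .check_count(n_samples, "n_samples", min = 2L),
    n_genes = .check_count(n_genes, "n_genes"),
    hox_gene_names = as.character(hox_gene_names),
    subtype2_fraction = .check_prob(subtype2_fraction, "subtype2_fraction",
                                    lo_open = TRUE, hi_open = TRUE),
    hox_shift = as.numeric(hox_shift),
    n_de_genes = .check_count(n_de_genes, "n_de_genes", min = 0L),
    de_shift = as.numeric(de_shift),
    noise_sd = as.numeric(noise_sd),
    n_batches = .check_count(n_batches, "n_batches"),
    batch_shift_sd = as.numeric(batch_shift_sd),
    baseline_median_survival = as.numeric(baseline_median_survival),
    subtype_hr = as.numeric(subtype_hr),
    censoring_rate = .check_prob(censoring_rate, "censoring_rate",
                                 hi_open = TRUE),
    mutation_rate_by_subtype = as.numeric(mutation_rate_by_subtype),
    seed = .check_count(seed, "seed", min = 0L)
  )
  if (length(spec$hox_gene_names) < 1L || anyDuplicated(spec$hox_gene_names)) {
    stop("'hox_gene_names' must be a nonempty set of unique identifiers",
         call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  if (spec$subtype_hr <= 0) stop("'subtype_hr' must be positive",
                                 call. = FALSE)
  if (spec$baseline_median_survival <= 0) {
    stop("'baseline_median_survival' must be positive", call. = FALSE)
  }
  if (spec$batch_shift_sd < 0) stop("'batch_shift_sd' must be nonnegative",
                                    call. = FALSE)
  if (length(spec$mutation_rate_by_subtype) != 2L ||
      any(spec$mutation_rate_by_subtype <= 0)) {
    stop("'mutation_rate_by_subtype' must be two positive means",
         call. = FALSE)
  }
  if (spec$n_de_genes + length(spec$hox_gene_names) > spec$n_genes) {
    stop("'n_de_genes' plus the HOX list exceeds 'n_genes'", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_samples, "samples x", x$n_genes,
      "genes\n")
  cat(sprintf("  subtype II fraction %.2f; HOX shift %.2g; %d DE genes (shift %.2g)\n",
              x$subtype2_fraction, x$hox_shift, x$n_de_genes, x$de_shift))
  cat(sprintf("  survival: median %.0f mo (subtype I), HR %.2f, censoring %.2f\n",
              x$baseline_median_survival, x$subtype_hr, x$censoring_rate))
  cat(sprintf("  %d batches (offset sd %.2g); mutation means %.1f / %.1f; seed %d\n",
              x$n_batches, x$batch_shift_sd, x$mutation_rate_by_subtype[1],
              x$mutation_rate_by_subtype[2], x$seed))
  invisible(x)
}

## Solve the upper bound b of Uniform(0, b) censoring so that the expected
## censored fraction over the subtype mixture equals the target rate.
## For T ~ Exp(r), C ~ U(0, b): P(C < T) = (1 - exp(-r b)) / (r b).
.censoring_bound <- function(rates, weights, target) {
  if (target <= 0) return(Inf)
  f <- function(b) {
    sum(weights * (1 - exp(-rates * b)) / (rates * b)) - target
  }
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from a [cohort_spec()]: Gaussian log2-scale expression with
#' planted subtype effects and additive batch offsets, exponential survival
#' with independent uniform censoring calibrated to the target censoring
#' rate, Poisson mutation counts, and a handful of CNV segments per sample.
#' Identical spec (including seed) gives an identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `expression` (gene x sample matrix, log2 scale), `clinical` (data frame
#'   with `sample_id`, `age_at_diagnosis`, `sex`, `who_grade`, `histology`,
#'   `os_months`, `os_event`), `true_subtype` (factor `"I"`/`"II"`),
#'   `true_de_genes`, `batch`, `mutation_count`, and `cnv_segments`
#'   (data frame with 0-based half-open coordinates and `segment_mean`).
#' @examples
#' ch <- generate_cohort(cohort_spec(n_samples = 40, n_genes = 120,
#'                                   n_de_genes = 20, seed = 7))
#' dim(ch$expression)
#' table(ch$true_subtype)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    n <- spec$n_samples
    sample_ids <- sprintf("S%03d", seq_len(n))
    subtype <- factor(ifelse(stats::runif(n) < spec$subtype2_fraction,
                             "II", "I"), levels = c("I", "II"))

    n_hox <- length(spec$hox_gene_names)
    n_null <- spec$n_genes - n_hox - spec$n_de_genes
    de_genes <- if (spec$n_de_genes > 0) {
      sprintf("DE%04d", seq_len(spec$n_de_genes))
    } else character(0)
    null_genes <- if (n_null > 0) sprintf("G%05d", seq_len(n_null)) else
      character(0)
    genes <- c(spec$hox_gene_names, de_genes, null_genes)

    # per-gene baseline levels on the log2 scale; drawn under a fixed
    # internal seed so that cohorts simulated with different seeds share
    # gene-level baselines (a gene's typical abundance is a property of the
    # gene, not of the cohort) and classifiers transfer across cohorts
    base <- with_seed(791L, stats::runif(spec$n_genes, min = 2, max = 8))
    expr <- matrix(stats::rnorm(spec$n_genes * n, mean = base,
                                sd = spec$noise_sd),
                   nrow = spec$n_genes, ncol = n,
                   dimnames = list(genes, sample_ids))
    is2 <- subtype == "II"
    if (any(is2)) {
      expr[spec$hox_gene_names, is2] <- expr[spec$hox_gene_names, is2,
                                             drop = FALSE] + spec$hox_shift
      if (spec$n_de_genes > 0) {
        expr[de_genes, is2] <- expr[de_genes, is2, drop = FALSE] +
          spec$de_shift
      }
    }

    batch <- factor(rep_len(seq_len(spec$n_batches), n))
    if (spec$n_batches > 1L && spec$batch_shift_sd > 0) {
      offs <- matrix(stats::rnorm(spec$n_genes * spec$n_batches, sd =
                                    spec$batch_shift_sd),
                     nrow = spec$n_genes)
      expr <- expr + offs[, as.integer(batch)]
    }

    # exponential survival: rate chosen so subtype I median matches spec
    rate1 <- log(2) / spec$baseline_median_survival
    rates <- ifelse(is2, rate1 * spec$subtype_hr, rate1)
    event_time <- stats::rexp(n, rate = rates)
    if (spec$censoring_rate > 0) {
      w <- c(1 - spec$subtype2_fraction, spec$subtype2_fraction)
      b <- .censoring_bound(c(rate1, rate1 * spec$subtype_hr), w,
                            spec$censoring_rate)
      cens_time <- stats::runif(n, 0, b)
    } else {
      cens_time <- rep(Inf, n)
    }
    os_months <- pmin(event_time, cens_time)
    os_event <- as.integer(event_time <= cens_time)

    mutation_count <- stats::rpois(
      n, lambda = spec$mutation_rate_by_subtype[as.integer(is2) + 1L])

    clinical <- data.frame(
      sample_id = sample_ids,
      age_at_diagnosis = round(stats::runif(n, 1, 19), 1),
      sex = sample(c("male", "female"), n, replace = TRUE),
      who_grade = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.2)),
      histology = sample(c("astrocytoma", "ependymoma", "medulloblastoma",
                           "glioblastoma"), n, replace = TRUE),
      os_months = os_months,
      os_event = os_event,
      stringsAsFactors = FALSE
    )

    # a few CNV segments per sample; segment means ~ N(0, 0.25)
    n_seg <- 3L
    seg_start <- matrix(sample.int(1e6, n * n_seg, replace = TRUE),
                        ncol = n_seg)
    cnv_segments <- data.frame(
      sample_id = rep(sample_ids, each = n_seg),
      chromosome = paste0("chr", sample(1:22, n * n_seg, replace = TRUE)),
      start = as.vector(t(seg_start)),
      end = as.vector(t(seg_start)) +
        sample.int(5e5, n * n_seg, replace = TRUE),
      segment_mean = round(stats::rnorm(n * n_seg, sd = 0.25), 4),
      stringsAsFactors = FALSE
    )

    structure(list(
      expression = expr,
      clinical = clinical,
      true_subtype = subtype,
      true_de_genes = de_genes,
      batch = batch,
      mutation_count = mutation_count,
      cnv_segments = cnv_segments,
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$expression), "samples x",
      nrow(x$expression), "genes\n")
  cat("  subtype I/II:", sum(x$true_subtype == "I"), "/",
      sum(x$true_subtype == "II"), "\n")
  cat("  events:", sum(x$clinical$os_event), "of", nrow(x$clinical),
      sprintf("(censoring %.2f)\n", mean(x$clinical$os_event == 0)))
  cat("  planted DE genes:", length(x$true_de_genes), "; batches:",
      nlevels(x$batch), "\n")
  invisible(x)
}

#' Generate named gene sets with planted subtype-differential activity
#'
#' Draws `n_sets` gene sets of size `set_size` from a cohort spec's gene
#' universe. The first `n_active` sets are sampled from the planted DE genes
#' (and therefore carry subtype-differential activity); the remainder are
#' sampled from null genes. A stand-in for curated oncogenic-pathway lists
#' in recovery experiments.
#'
#' @param spec a [cohort_spec()] (the same one used for the cohort).
#' @param n_sets number of gene sets.
#' @param set_size genes per set.
#' @param n_active number of sets drawn from planted DE genes.
#' @param seed RNG seed (defaults to `spec$seed + 1`).
#' @return named list of character vectors; names `SET01`, ... Active sets
#'   carry attribute `active = TRUE` entries in `attr(, "active")`.
#' @export
generate_gene_sets <- function(spec, n_sets = 10L, set_size = 20L,
                               n_active = 3L, seed = spec$seed + 1L) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec",
                                           call. = FALSE)
  n_sets <- .check_count(n_sets, "n_sets")
  set_size <- .check_count(set_size, "set_size")
  n_active <- .check_count(n_active, "n_active", min = 0L)
  if (set_size > spec$n_genes) {
    stop("'set_size' exceeds the number of genes in the spec", call. = FALSE)
  }
  if (n_active > n_sets) stop("'n_active' exceeds 'n_sets'", call. = FALSE)
  de_genes <- if (spec$n_de_genes > 0) sprintf("DE%04d",
                                               seq_len(spec$n_de_genes))
    else character(0)
  n_null <- spec$n_genes - length(spec$hox_gene_names) - spec$n_de_genes
  null_genes <- if (n_null > 0) sprintf("G%05d", seq_len(n_null)) else
    character(0)
  if (n_active > 0 && length(de_genes) < set_size) {
    stop("not enough planted DE genes to fill an active set", call. = FALSE)
  }
  if (n_active < n_sets && length(null_genes) < set_size) {
    stop("not enough null genes to fill an inactive set", call. = FALSE)
  }
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      pool <- if (i <= n_active) de_genes else null_genes
      sample(pool, set_size)
    })
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    attr(sets, "active") <- seq_len(n_sets) <= n_active
    sets
  })
}
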