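# Synthetic-data generators: EMT-induction expression time courses,
# two-group tumour cohorts with planted module-activity shifts, and
# random Boolean models for oracle testing. All generators are
# deterministic under a fixed seed and return the ground truth needed
# to check downstream analyses.

#' Default sigmoid parameters of the EMT-induction time course
#'
#' One row per dynamically expressed gene: log2 baseline, signed
#' amplitude (negative = repression, e.g. the loss of E-cadherin),
#' sigmoid midpoint time (hours) and slope (per hour). Midpoints are
#' staggered so that the 8 h timepoint sits near the epithelial /
#' mesenchymal decision boundary: TGF-beta ligand and SMAD respond
#' first, the core EMT regulators and mesenchymal markers mid-course,
#' and E-cadherin is lost late.
#'
#' @return Data frame with columns `gene`, `baseline`, `amplitude`,
#'   `midpoint`, `slope`.
#' @export
default_timecourse_genes <- function() {
  data.frame(
    gene      = c("TGFB1", "SMAD3", "SNAI2", "EGFR", "MAPK1", "VIM",
                  "CDH2", "ZEB1", "CTNNB1", "MMP2", "CDH1"),
    baseline  = c(6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 10),
    amplitude = c(4, 4, 4, 4, 4, 4, 4, 4, 4, 4, -4),
    midpoint  = c(4, 6, 10, 12, 12, 14, 16, 18, 20, 20, 40),
    slope     = c(0.5, 0.4, 0.35, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.15))
}

default_static_genes <- function() {
  c(TP53 = 4, TP63 = 4, TP73 = 4, MIR200C = 4, MIR203A = 4, MIR34A = 4,
    NOTCH1 = 4, DKK1 = 4, AKT1 = 4, CDKN1A = 4,
    AKT2 = 9, CASP9 = 9, CDC42 = 9, SNAI1 = 9, TWIST1 = 9, ZEB2 = 9)
}

#' Time-course generator specification
#'
#' @param timepoints sampling times in hours.
#' @param n_replicates replicates per timepoint.
#' @param dynamic_genes data frame of per-gene sigmoid parameters (see
#'   [default_timecourse_genes()]).
#' @param static_genes named numeric vector of constant log2 levels.
#' @param noise_sd additive Gaussian noise on log expression
#'   (multiplicative on the raw scale).
#' @param seed RNG seed.
#' @return A `timecourse_spec` list.
#' @export
timecourse_spec <- function(timepoints = c(0, 8, 24, 72), n_replicates = 3,
                            dynamic_genes = default_timecourse_genes(),
                            static_genes = default_static_genes(),
                            noise_sd = 0.25, seed = 1) {
  stopifnot(noise_sd >= 0, n_replicates >= 1, length(timepoints) >= 1,
            all(c("gene", "baseline", "amplitude", "midpoint", "slope") %in%
                  names(dynamic_genes)),
            all(is.finite(dynamic_genes$amplitude)),
            all(dynamic_genes$slope > 0))
  structure(list(timepoints = timepoints, n_replicates = as.integer(n_replicates),
                 dynamic_genes = dynamic_genes, static_genes = static_genes,
                 noise_sd = noise_sd, seed = seed),
            class = "timecourse_spec")
}

sigmoid_level <- function(baseline, amplitude, midpoint, slope, t) {
  baseline + amplitude / (1 + exp(-slope * (t - midpoint)))
}

#' Generate a synthetic EMT-induction expression time course
#'
#' Dynamic genes follow sigmoid trajectories (in log2 expression) with
#' additive Gaussian noise; static genes stay at their constant level
#' plus noise. With the default parameters the early timepoints
#' binarize toward the epithelial / apoptotic stable-state patterns and
#' the late timepoints toward the metastatic one.
#'
#' @param spec a [timecourse_spec()].
#' @return List with `expr` (an `expr_matrix` with timepoint/replicate
#'   annotations) and `truth`: the spec's gene table plus `true_bits`,
#'   the noise-free ON/OFF call of each dynamic gene at each timepoint
#'   (value above the sigmoid midpoint level).
#' @export
generate_timecourse <- function(spec = timecourse_spec()) {
  set.seed(spec$seed)
  tps <- rep(spec$timepoints, each = spec$n_replicates)
  reps <- rep(seq_len(spec$n_replicates), times = length(spec$timepoints))
  dg <- spec$dynamic_genes
  clean_dynamic <- t(vapply(seq_len(nrow(dg)), function(i) {
    sigmoid_level(dg$baseline[i], dg$amplitude[i], dg$midpoint[i], dg$slope[i], tps)
  }, numeric(length(tps))))
  rownames(clean_dynamic) <- dg$gene
  clean_static <- matrix(rep(spec$static_genes, length(tps)),
                         nrow = length(spec$static_genes),
                         dimnames = list(names(spec$static_genes), NULL))
  clean <- rbind(clean_dynamic, clean_static)
  values <- clean + matrix(rnorm(length(clean), sd = spec$noise_sd),
                           nrow = nrow(clean))
  colnames(values) <- paste0("T", tps, "_r", reps)
  expr <- expr_matrix(values, timepoint = tps, replicate = reps)

  true_bits <- t(vapply(seq_len(nrow(dg)), function(i) {
    lv <- sigmoid_level(dg$baseline[i], dg$amplitude[i], dg$midpoint[i], dg$slope[i],
                        spec$timepoints)
    as.integer(lv >= dg$baseline[i] + dg$amplitude[i] / 2)
  }, integer(length(spec$timepoints))))
  dimnames(true_bits) <- list(dg$gene, paste0("T", spec$timepoints))

  list(expr = expr, truth = list(dynamic_genes = dg, static_genes = spec$static_genes,
                                 true_bits = true_bits))
}

#' Cohort generator specification
#'
#' Defaults emulate a two-group tumour cohort of 88 non-metastatic (M0)
#' and 17 metastatic (M1) samples with planted module-activity shifts.
#'
#' @param n_group0,n_group1 group sizes.
#' @param effects named numeric vector of planted per-module shifts in
#'   pooled-SD units (positive = more active in group 1).
#' @param n_target_genes synthetic target genes generated per module.
#' @param n_background unaffected background genes.
#' @param noise_sd per-gene, per-sample Gaussian noise SD (the pooled SD
#'   that effect sizes are expressed in).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   levels.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_group0 = 88, n_group1 = 17,
                        effects = c(AKT2 = 1, miRNA = -1),
                        n_target_genes = 10, n_background = 50,
                        noise_sd = 1, baseline_mean = 8, baseline_sd = 1.5,
                        seed = 1) {
  stopifnot(n_group0 >= 2, n_group1 >= 2, all(is.finite(effects)),
            n_target_genes >= 1, noise_sd > 0)
  structure(list(n_group0 = as.integer(n_group0), n_group1 = as.integer(n_group1),
                 effects = effects, n_target_genes = as.integer(n_target_genes),
                 n_background = as.integer(n_background), noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic two-group expression cohort
#'
#' Each module gets `n_target_genes` synthetic target genes at
#' log-normal baseline expression with i.i.d. Gaussian noise; modules
#' named in `spec$effects` additionally shift all their target genes by
#' `effect * noise_sd` in group-1 samples, planting a module-activity
#' difference of known sign and size.
#'
#' @param spec a [cohort_spec()].
#' @param modules module names to generate target-gene sets for;
#'   defaults to the bundled pathway modules.
#' @return List with `expr` (an `expr_matrix` with group annotation
#'   `M0`/`M1`), `modules` (named list of target-gene sets, suitable for
#'   [activity_scores()]) and `truth` (the planted effects).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            modules = names(metastasis_modules())) {
  unknown <- setdiff(names(spec$effects), modules)
  if (length(unknown)) stop("planted effect on undefined module(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(spec$seed)
  gene_sets <- setNames(lapply(modules, function(m) {
    paste0(m, "_T", sprintf("%02d", seq_len(spec$n_target_genes)))
  }), modules)
  genes <- c(unlist(gene_sets, use.names = FALSE),
             if (spec$n_background > 0)
               paste0("BG_", sprintf("%03d", seq_len(spec$n_background))))
  n <- spec$n_group0 + spec$n_group1
  group <- rep(c("M0", "M1"), c(spec$n_group0, spec$n_group1))
  baseline <- rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)
  values <- matrix(rnorm(length(genes) * n, sd = spec$noise_sd),
                   nrow = length(genes)) + baseline
  rownames(values) <- genes
  colnames(values) <- paste0(group, "_", sprintf("%03d", seq_len(n)))
  for (m in names(spec$effects)) {
    shift <- spec$effects[[m]] * spec$noise_sd
    values[gene_sets[[m]], group == "M1"] <-
      values[gene_sets[[m]], group == "M1"] + shift
  }
  list(expr = expr_matrix(values, group = group),
       modules = gene_sets,
       truth = list(effects = spec$effects))
}

#' Generate a random Boolean model
#'
#' Each node receives a rule over 1 to `max_regulators` randomly chosen
#' regulators, combined left-to-right with random AND/OR connectors and
#' random negations; the model is emitted as rule-file text and parsed
#' back, so every generated model exercises the parser. Intended for
#' oracle testing against brute-force enumeration at small `n_nodes`.
#'
#' @param n_nodes number of nodes.
#' @param max_regulators maximum regulators per rule.
#' @param seed RNG seed.
#' @param n_inputs number of input (free constant) nodes.
#' @return A `boolean_model`.
#' @export
generate_random_model <- function(n_nodes, max_regulators = 3, seed = 1,
                                  n_inputs = 0) {
  stopifnot(n_nodes >= 1, max_regulators >= 1, n_inputs < n_nodes)
  set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  inputs <- head(nodes, n_inputs)
  lines <- if (n_inputs > 0) paste("input", inputs) else character()
  for (nd in setdiff(nodes, inputs)) {
    k <- sample.int(max_regulators, 1L)
    regs <- sample(nodes, k, replace = FALSE)
    lits <- ifelse(runif(k) < 0.3, paste0("!", regs), regs)
    expr <- lits[1]
    if (k > 1L) {
      ops <- sample(c("&", "|"), k - 1L, replace = TRUE)
      for (j in 2:k) expr <- paste(expr, ops[j - 1L], lits[j])
    }
    lines <- c(lines, paste(nd, "=", expr))
  }
  parse_boolean_model(lines)
}
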