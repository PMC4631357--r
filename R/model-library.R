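# The bundled metastasis model: rules, phenotype semantics, pathway
# modules and the biomarker/gene mapping used for expression matching.

metastasis_extdata <- function(file) {
  path <- system.file("extdata", file, package = "boolmet")
  if (!nzchar(path)) stop("bundled data file not found: ", file, call. = FALSE)
  path
}

#' Phenotype read-out nodes of the metastasis model
#'
#' The six output variables whose ON-probability is the readout of the
#' model: cell-cycle arrest, apoptosis, and the metastasis cascade
#' (EMT, invasion, migration, metastasis).
#'
#' @return Character vector of node names.
#' @export
phenotype_nodes <- function() {
  c("Apoptosis", "CellCycleArrest", "EMT", "Invasion", "Migration", "Metastasis")
}

#' Load the bundled metastasis model
#'
#' A 32-node logical model of the early steps of metastasis: EMT,
#' invasion and migration of tumour cells, with two free inputs
#' (extracellular microenvironment, DNA damage) and six phenotype
#' read-out nodes. "ECM" is aliased to "ECMicroenv". The model has nine
#' wild-type stable states (see [metastasis_stable_states()]).
#'
#' @return A `boolean_model` with 32 nodes.
#' @export
#' @examples
#' m <- load_metastasis_model()
#' length(m$nodes)
load_metastasis_model <- function() {
  model <- read_boolean_model(metastasis_extdata("metastasis_rules.txt"),
                              aliases = c(ECM = "ECMicroenv"))
  if (length(model$nodes) != 32L) {
    stop("bundled model fixture is corrupted: expected 32 nodes, found ",
         length(model$nodes), call. = FALSE)
  }
  model
}

#' The nine wild-type stable states of the metastasis model
#'
#' Returns the bundled reference table of the nine stable states of the
#' wild-type model, one column per state (HS, Apop1-4, EMT1-2, M1-2),
#' one row per node.
#'
#' @return Integer matrix, 32 nodes x 9 states.
#' @export
metastasis_stable_states <- function() {
  read_stable_states(metastasis_extdata("wildtype_stable_states.tsv"))
}

#' Label a stable state with its phenotype
#'
#' Labels are assigned from the six phenotype nodes, plus CDH1 for the
#' homeostatic state: `HS` when all six phenotype nodes are OFF and CDH1
#' is ON (the epithelial state in which metastasis is held off by
#' E-cadherin); `Metastasis` when the Metastasis node is ON (which
#' requires EMT, Invasion and Migration all ON);
#' `Apoptosis+CellCycleArrest` and `EMT+CellCycleArrest` for the
#' apoptotic and EMT-arrested states. Any other pattern is labelled
#' `other` with the set of active outputs attached as an attribute.
#'
#' @param state a network state covering at least the phenotype nodes
#'   and CDH1 (named 0/1 vector).
#' @return Character label, with attribute `active_outputs`.
#' @export
label_stable_state <- function(state) {
  ph <- phenotype_nodes()
  missing <- setdiff(c(ph, "CDH1"), names(state))
  if (length(missing)) {
    stop("state is missing node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  active <- ph[state[ph] == 1L]
  label <- if (length(active) == 0L && state[["CDH1"]] == 1L) {
    "HS"
  } else if (state[["Metastasis"]] == 1L &&
             all(state[c("EMT", "Invasion", "Migration")] == 1L)) {
    "Metastasis"
  } else if (setequal(active, c("Apoptosis", "CellCycleArrest"))) {
    "Apoptosis+CellCycleArrest"
  } else if (setequal(active, c("EMT", "CellCycleArrest"))) {
    "EMT+CellCycleArrest"
  } else {
    "other"
  }
  structure(label, active_outputs = active)
}

#' Pathway modules of the metastasis model
#'
#' The signalling-pathway modules used by the modular analyses: each
#' module lumps the model nodes of one pathway (TGF-beta, Notch, Wnt,
#' p53, p63/p73, the microRNAs, the core EMT regulators, E-cadherin,
#' growth factors, ERK, and the two AKT isoforms).
#'
#' @return Named list of character vectors (module -> member nodes).
#' @export
metastasis_modules <- function() {
  lines <- readLines(metastasis_extdata("modules.tsv"), warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
           vapply(parts, `[[`, character(1), 1))
}

#' Clamp set realising a pathway-level mutant
#'
#' A gain of function (GoF) of a pathway clamps every member node ON, a
#' loss of function (LoF) clamps every member OFF, mirroring the idea
#' that altering an important entity of a pathway affects the whole
#' pathway's activity.
#'
#' @param module module name (see [metastasis_modules()]) or a character
#'   vector of member nodes.
#' @param direction `"GoF"` or `"LoF"`.
#' @param modules named list of module definitions; defaults to the
#'   bundled ones.
#' @return Named 0/1 clamp vector.
#' @export
#' @examples
#' module_clamps("TGFb_pthw", "LoF")
module_clamps <- function(module, direction = c("GoF", "LoF"),
                          modules = metastasis_modules()) {
  direction <- match.arg(direction)
  members <- if (length(module) == 1L && module %in% names(modules)) {
    modules[[module]]
  } else if (length(module) == 1L) {
    stop("unknown module: ", module, call. = FALSE)
  } else {
    module
  }
  setNames(rep(if (direction == "GoF") 1L else 0L, length(members)), members)
}

#' Node-to-gene mapping for expression matching
#'
#' Maps model nodes to HUGO gene symbols. Most nodes are named after
#' their gene; phenotype read-outs map to biomarkers (Apoptosis ->
#' CASP9, Migration -> CDC42, Invasion -> MMP2) and GF / ERK map to the
#' closest measured species (EGFR, MAPK1). The defaults can be
#' overridden by supplying a modified table to the matching functions.
#'
#' @return Named character vector (node -> gene symbol).
#' @export
metastasis_gene_map <- function() {
  df <- read.delim(metastasis_extdata("gene_map.tsv"), header = FALSE,
                   comment.char = "#", col.names = c("node", "gene"))
  setNames(df$gene, df$node)
}

#' Biomarker genes for the phenotype read-outs
#'
#' @return Named character vector: Apoptosis -> CASP9, Migration ->
#'   CDC42, Invasion -> MMP2.
#' @export
biomarker_map <- function() {
  c(Apoptosis = "CASP9", Migration = "CDC42", Invasion = "MMP2")
}

#' Genes with significant expression dynamics during EMT induction
#'
#' The eleven model-mappable genes whose expression follows a sigmoid
#' induction (or loss) trajectory during a TGF-beta EMT-induction time
#' course; the remaining mapped genes stay above or below threshold
#' throughout.
#'
#' @return Character vector of HUGO symbols.
#' @export
emt_dynamic_genes <- function() {
  c("CDH1", "CDH2", "CTNNB1", "EGFR", "MAPK1", "MMP2", "SMAD3", "SNAI2",
    "TGFB1", "VIM", "ZEB1")
}
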