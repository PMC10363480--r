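#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet width
#' @include utils.R
NULL

PEPTIDE_ROLES <- c("HA_RAMP", "mTP", "cTP", "RANDOM", "CONSTRUCT",
                   "ELEMENT", "OTHER")

TARGETING_LEVELS <- c("NONE", "PARTIAL", "FULL")

#' PeptideSet: an annotated collection of peptides
#'
#' The central container of the package: an ordered set of peptide sequences
#' over the 20-letter amino-acid alphabet, each carrying a unique id, a role
#' (\code{HA_RAMP}, \code{mTP}, \code{cTP}, \code{RANDOM}, \code{CONSTRUCT},
#' \code{ELEMENT} or \code{OTHER}), an optional 1-based cleavage-site index
#' (the last residue of the presequence; cleavage occurs after it), an
#' optional family label, and an optional annotated helix span
#' (\code{helix_start}/\code{helix_end}, used for targeting-peptide records
#' whose helix is known from structural work).
#'
#' Sequences are stored as a \linkS4class{AAStringSet}; per-peptide
#' annotations live in a parallel \code{DataFrame}.
#'
#' @slot sequences an \code{AAStringSet}, names are the peptide ids
#' @slot meta a \code{DataFrame} with columns \code{role}, \code{cleavage},
#'   \code{family}, \code{helix_start}, \code{helix_end}
#' @slot setName single string naming the set
#' @slot provenance free-text provenance note
#'
#' @seealso \code{\link{PeptideSet}} (constructor),
#'   \code{\link{readPeptides}}, \code{\link{substituteBasic}}
#' @name PeptideSet-class
#' @rdname PeptideSet-class
#' @exportClass PeptideSet
setClass("PeptideSet",
  representation(
    sequences = "AAStringSet",
    meta = "DataFrame",
    setName = "character",
    provenance = "character"
  )
)

setValidity("PeptideSet", function(object) {
  ids <- names(object@sequences)
  n <- length(object@sequences)
  msg <- character()
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    msg <- c(msg, "every peptide needs a non-empty id")
  else if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate peptide id(s): ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per peptide")
  need <- c("role", "cleavage", "family", "helix_start", "helix_end")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste0("meta must have columns: ", paste(need, collapse = ", ")))
  if (length(msg)) return(msg)
  if (n) {
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "sequences must be non-empty")
    seqs <- as.character(object@sequences)
    bad <- vapply(seqs, function(s) {
      r <- strsplit(s, "", fixed = TRUE)[[1]]
      w <- which(!(r %in% AA20))
      if (length(w)) w[1L] else 0L
    }, integer(1))
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      msg <- c(msg, paste0("record '", ids[i], "': non-standard residue at position ",
                           bad[i]))
    }
    cl <- object@meta$cleavage
    w <- Biostrings::width(object@sequences)
    off <- !is.na(cl) & (cl < 1L | cl > w)
    if (any(off))
      msg <- c(msg, paste0("cleavage index out of range for: ",
                           paste(ids[off], collapse = ", ")))
    if (any(!(object@meta$role %in% PEPTIDE_ROLES)))
      msg <- c(msg, paste0("role must be one of: ",
                           paste(PEPTIDE_ROLES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' HelixProfile: amphipathic-helix annotations for one peptide
#'
#' Result of \code{\link{findAmphipathicHelices}}: the non-overlapping
#' amphipathic alpha-helix annotations found in a peptide, together with the
#' summary quantities used for comparing targeting-peptide classes.
#'
#' @slot peptide_id the peptide's id
#' @slot annotations data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive), \code{mu_h} (per-residue hydrophobic moment),
#'   \code{angle} (moment direction, degrees, window-local frame),
#'   \code{source} (\code{PREDICTED} or \code{EXTERNAL}),
#'   \code{face_hydrophobic} and \code{face_hydrophilic} (comma-separated
#'   residue indices); sorted by \code{start}, pairwise non-overlapping
#' @slot helix_fraction fraction of the evaluated sequence covered by
#'   annotations, in [0, 1]
#' @slot upstream_length residues before the longest annotated helix; for a
#'   helix-free peptide this is the whole evaluated length by convention
#'   (see \code{helix_free})
#' @slot evaluation_limit number of N-terminal residues evaluated (the
#'   cleavage index for targeting peptides, otherwise the full length)
#' @slot helix_free TRUE when no helix qualified, flagging that
#'   \code{upstream_length} is the convention value
#' @name HelixProfile-class
#' @rdname HelixProfile-class
#' @exportClass HelixProfile
setClass("HelixProfile",
  representation(
    peptide_id = "character",
    annotations = "data.frame",
    helix_fraction = "numeric",
    upstream_length = "numeric",
    evaluation_limit = "integer",
    helix_free = "logical"
  )
)

setValidity("HelixProfile", function(object) {
  a <- object@annotations
  msg <- character()
  if (nrow(a)) {
    if (any(a$start > a$end)) msg <- c(msg, "annotation start > end")
    if (is.unsorted(a$start)) msg <- c(msg, "annotations must be sorted by start")
    if (nrow(a) > 1L && any(a$start[-1L] <= a$end[-nrow(a)]))
      msg <- c(msg, "annotations must not overlap")
    if (any(a$mu_h < 0)) msg <- c(msg, "mu_h must be non-negative")
  }
  if (object@helix_fraction < 0 || object@helix_fraction > 1)
    msg <- c(msg, "helix_fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConstructSpec: one cell of the chimeric-construct grammar
#'
#' Describes a chimeric construct as (core peptide, basic-residue variant,
#' optional N-terminal cTP element, optional C-terminal TP element), plus
#' its grid coordinates where the core is part of the canonical series.
#' Cores are the 13 HA-RAMP codes, the TP helical fragments \code{CH} /
#' \code{MH}, the random peptides \code{RP1} / \code{RP2}, the poly-alanine
#' token \code{AA}, or \code{-} (no core: N- and C-elements fused directly).
#'
#' @slot core_id core token
#' @slot basic_variant \code{NATIVE}, \code{K} or \code{R}
#' @slot n_element \code{NONE} or \code{CTP_N}
#' @slot c_element \code{NONE}, \code{CTP_C} or \code{MTP_C}
#' @slot row grid row letter A-L (NA when undefined for the variant)
#' @slot column grid column letter a-s (NA for non-canonical cores)
#' @seealso \code{\link{parseConstructCode}}, \code{\link{assembleConstruct}}
#' @name ConstructSpec-class
#' @rdname ConstructSpec-class
#' @exportClass ConstructSpec
setClass("ConstructSpec",
  representation(
    core_id = "character",
    basic_variant = "character",
    n_element = "character",
    c_element = "character",
    row = "character",
    column = "character"
  )
)

setValidity("ConstructSpec", function(object) {
  msg <- character()
  if (!(object@basic_variant %in% c("NATIVE", "K", "R")))
    msg <- c(msg, "basic_variant must be NATIVE, K or R")
  if (!(object@n_element %in% c("NONE", "CTP_N")))
    msg <- c(msg, "n_element must be NONE or CTP_N")
  if (!(object@c_element %in% c("NONE", "CTP_C", "MTP_C")))
    msg <- c(msg, "c_element must be NONE, CTP_C or MTP_C")
  if (length(msg)) msg else TRUE
})

#' TargetingGrid: curated construct-targeting outcomes
#'
#' Holds per-construct organelle-targeting calls for the chimeric construct
#' series: rows A-L encode the modification scheme (basic-residue variant
#' and added TP elements), columns a-s the core peptide (a-m the 13
#' HA-RAMPs, n-o random peptides, p-s TP-derived controls). Each cell
#' carries a mitochondrial and a chloroplast call, each \code{NONE},
#' \code{PARTIAL} or \code{FULL} (ordered); dual targeting is derived, not
#' stored: both calls at least \code{PARTIAL}.
#'
#' @slot calls data.frame with columns \code{row}, \code{column},
#'   \code{core}, \code{mito}, \code{chloro}, \code{note}
#' @seealso \code{\link{loadGrid}}, \code{\link{compareKRPairs}},
#'   \code{\link{tallyGrid}}, \code{\link{specificitySummary}}
#' @name TargetingGrid-class
#' @rdname TargetingGrid-class
#' @exportClass TargetingGrid
setClass("TargetingGrid", representation(calls = "data.frame"))

setValidity("TargetingGrid", function(object) {
  g <- object@calls
  msg <- character()
  need <- c("row", "column", "core", "mito", "chloro", "note")
  if (!all(need %in% names(g)))
    return(paste0("calls must have columns: ", paste(need, collapse = ", ")))
  if (nrow(g)) {
    if (any(!(g$row %in% LETTERS[1:12])))
      msg <- c(msg, "rows must be letters A-L")
    if (any(!(g$column %in% letters[1:19])))
      msg <- c(msg, "columns must be letters a-s")
    bad <- !(g$mito %in% TARGETING_LEVELS) | !(g$chloro %in% TARGETING_LEVELS)
    if (any(bad)) {
      i <- which(bad)[1L]
      msg <- c(msg, paste0("invalid targeting call at cell (", g$row[i], ", ",
                           g$column[i], ")"))
    }
    key <- paste(g$row, g$column)
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicate cell(s): ",
                           paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (length(msg)) msg else TRUE
})

#' ClassifierReport: outcome of the resampled cross-validation protocol
#'
#' @slot run_accuracies per-run mean held-out accuracies
#' @slot coefficients fitted weights (intercept first) from a final fit on
#'   all balanced data
#' @slot config the \code{\link{classifierConfig}} used
#' @slot seed the seed used (NA when none)
#' @slot n_redraws number of degenerate single-class folds that forced a
#'   re-draw
#' @name ClassifierReport-class
#' @rdname ClassifierReport-class
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(
    run_accuracies = "numeric",
    coefficients = "numeric",
    config = "list",
    seed = "integer",
    n_redraws = "integer"
  )
)

setValidity("ClassifierReport", function(object) {
  a <- object@run_accuracies
  if (length(a) && (any(a < 0) || any(a > 1)))
    "run accuracies must lie in [0, 1]" else TRUE
})
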