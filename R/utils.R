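## Internal helpers shared across modules.

# The 20 standard amino acids, one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Run an expression under a temporary RNG state
#'
#' Evaluates \code{expr} with the RNG seeded at \code{seed}, restoring the
#' caller's \code{.Random.seed} afterwards so seeded package functions never
#' perturb the global RNG stream. With \code{seed = NULL} the expression is
#' evaluated as-is.
#'
#' @param seed single integer or \code{NULL}
#' @param expr expression to evaluate
#' @return the value of \code{expr}
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Read a two-or-more column residue table shipped under extdata.
.readScaleFile <- function(file, value_cols) {
  path <- system.file("extdata", file, package = "chimeraTP", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", value_cols) %in% names(tab)))
  missing <- setdiff(AA20, tab$residue)
  if (length(missing))
    stop("scale table '", file, "' lacks residues: ",
         paste(missing, collapse = ", "))
  tab
}

.checkScale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale)))
    stop("scale must be a named numeric vector")
  missing <- setdiff(AA20, names(scale))
  if (length(missing))
    stop("scale lacks residues: ", paste(missing, collapse = ", "))
  invisible(scale)
}

# Split a sequence string into its residue characters.
.residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Error if a sequence contains a character outside the 20-letter alphabet,
# reporting the 1-based position of the first offender.
.checkAlphabet <- function(seq, id = "<peptide>") {
  res <- .residues(seq)
  bad <- which(!(res %in% AA20))
  if (length(bad))
    stop("record '", id, "': non-standard residue '", res[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  invisible(TRUE)
}

#' Amino-acid scale tables
#'
#' Loaders for the residue scales shipped with the package:
#' \describe{
#'   \item{\code{zScaleTable()}}{the classical three-component Z-scales
#'     (Hellberg-type), one row per residue with columns \code{z1} (roughly
#'     hydrophobicity), \code{z2} (steric bulk) and \code{z3} (electronic
#'     properties); returned as a 20 x 3 numeric matrix with residue
#'     rownames.}
#'   \item{\code{helixHydrophobicityScale()}}{the Fauchere-Pliska
#'     octanol/water hydrophobicity scale used for helical-wheel
#'     hydrophobic moments.}
#'   \item{\code{bomanScale()}}{per-residue protein-interaction propensities
#'     (kcal/mol); the Boman index is their sequence mean, high values
#'     indicating a preference for protein over lipid interaction.}
#'   \item{\code{hsp70AffinityScale()}}{a synthetic stand-in for
#'     experimentally derived per-residue Hsp70 binding affinities
#'     (the published values are not redistributed here); constructed to
#'     favour hydrophobic, leucine-rich heptamers and disfavour acidic
#'     residues, which is the qualitative behaviour of the chaperone's
#'     substrate-binding cleft. Higher scores mean stronger predicted
#'     binding.}
#' }
#'
#' @return \code{zScaleTable} a numeric matrix; the others a named numeric
#'   vector over the 20 standard residues.
#' @examples
#' zScaleTable()["K", ]
#' helixHydrophobicityScale()[c("L", "K")]
#' @export
zScaleTable <- function() {
  tab <- .readScaleFile("zscales.tsv", c("z1", "z2", "z3"))
  m <- as.matrix(tab[, c("z1", "z2", "z3")])
  rownames(m) <- tab$residue
  m[AA20, , drop = FALSE]
}

#' @rdname zScaleTable
#' @export
helixHydrophobicityScale <- function() {
  tab <- .readScaleFile("hydrophobicity_heliquest.tsv", "value")
  stats::setNames(tab$value, tab$residue)[AA20]
}

#' @rdname zScaleTable
#' @export
bomanScale <- function() {
  tab <- .readScaleFile("boman.tsv", "value")
  stats::setNames(tab$value, tab$residue)[AA20]
}

#' @rdname zScaleTable
#' @export
hsp70AffinityScale <- function() {
  tab <- .readScaleFile("hsp70_affinity_synthetic.tsv", "value")
  stats::setNames(tab$value, tab$residue)[AA20]
}
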