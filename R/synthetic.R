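#' @include helix-finder.R
NULL

# Background residue frequencies for RANDOM peptides: flat over the 20
# residues with acidic residues handled by acidic_rate like other classes.
.RANDOM_POOL <- setdiff(AA20, c("D", "E"))

# Unstructured-region residue pool (loop/coil formers plus the basic residue).
.UNSTRUCTURED_POOL <- c("S", "T", "P", "G", "A")
.HELIX_HYDRO_POOL <- c("L", "I", "V", "F", "A")
.HELIX_POLAR_POOL <- c("S", "T", "N", "Q", "G")

#' Specification for one synthetic peptide class
#'
#' Describes a class of seeded synthetic peptides whose statistical
#' structure mirrors the contrasts between targeting-peptide classes:
#' \code{MTP_LIKE} peptides are short (mean 37 residues), R-rich and
#' amphipathically helical from residue 1 over ~80\% of their length;
#' \code{CTP_LIKE} peptides are longer (mean 49), with an unstructured
#' N-terminal stretch (mean 15 residues, the cTP-N length) before a
#' central helix and a short unstructured tail; \code{HARAMP_LIKE}
#' peptides are K-rich and fully helical; \code{RANDOM} peptides draw
#' residues i.i.d. All classes are depleted of acidic residues
#' (\code{acidic_rate}, default 0.01).
#'
#' @param class_name \code{MTP_LIKE}, \code{CTP_LIKE}, \code{HARAMP_LIKE}
#'   or \code{RANDOM}
#' @param n number of peptides
#' @param length_mean,length_sd peptide length distribution (residues);
#'   class defaults 37/8 (mTP-like), 49/8 (cTP-like), 28/6 (HA-RAMP-like),
#'   40/10 (random)
#' @param upstream_mean,upstream_sd unstructured N-terminal prefix length
#'   (cTP-like only; 0 for mTP-like)
#' @param helix_arc angular width of the hydrophobic face, degrees
#' @param helix_cover fraction of the (post-prefix) sequence occupied by
#'   the designed helix (mTP-like default 0.8)
#' @param basic_residue \code{K} or \code{R}
#' @param acidic_rate target D+E frequency
#' @param seed integer seed for this class
#' @return a \code{generatorSpec} list
#' @export
generatorSpec <- function(class_name = c("MTP_LIKE", "CTP_LIKE",
                                         "HARAMP_LIKE", "RANDOM"),
                          n = 40L, length_mean = NULL, length_sd = NULL,
                          upstream_mean = NULL, upstream_sd = NULL,
                          helix_arc = 180, helix_cover = NULL,
                          basic_residue = NULL, acidic_rate = 0.01,
                          seed = 1L) {
  class_name <- match.arg(class_name)
  defaults <- switch(class_name,
    MTP_LIKE = list(length_mean = 37, length_sd = 8, upstream_mean = 0,
                    upstream_sd = 0, helix_cover = 0.8, basic_residue = "R"),
    CTP_LIKE = list(length_mean = 49, length_sd = 8, upstream_mean = 15,
                    upstream_sd = 4, helix_cover = 0.55, basic_residue = "R"),
    HARAMP_LIKE = list(length_mean = 28, length_sd = 6, upstream_mean = 0,
                       upstream_sd = 0, helix_cover = 1, basic_residue = "K"),
    RANDOM = list(length_mean = 40, length_sd = 10, upstream_mean = 0,
                  upstream_sd = 0, helix_cover = 0, basic_residue = "K"))
  spec <- list(class_name = class_name, n = as.integer(n),
               length_mean = length_mean %||% defaults$length_mean,
               length_sd = length_sd %||% defaults$length_sd,
               upstream_mean = upstream_mean %||% defaults$upstream_mean,
               upstream_sd = upstream_sd %||% defaults$upstream_sd,
               helix_arc = helix_arc,
               helix_cover = helix_cover %||% defaults$helix_cover,
               basic_residue = basic_residue %||% defaults$basic_residue,
               acidic_rate = acidic_rate, seed = as.integer(seed))
  stopifnot(spec$n >= 1L, spec$helix_arc > 60, spec$helix_arc < 300)
  class(spec) <- "generatorSpec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample one helical stretch of `len` residues on the wheel, hydrophobic
# face of width `arc` degrees centred at 0.
.sampleHelix <- function(len, arc, basic, delta = 100) {
  ang <- ((seq_len(len) - 1L) * delta) %% 360
  dist0 <- pmin(ang, 360 - ang)
  hydro <- dist0 <= arc / 2
  out <- character(len)
  out[hydro] <- sample(.HELIX_HYDRO_POOL, sum(hydro), replace = TRUE)
  n_pol <- sum(!hydro)
  if (n_pol) {
    use_basic <- stats::runif(n_pol) < 0.5
    pol <- character(n_pol)
    pol[use_basic] <- basic
    pol[!use_basic] <- sample(.HELIX_POLAR_POOL, sum(!use_basic),
                              replace = TRUE)
    out[!hydro] <- pol
  }
  out
}

.sampleUnstructured <- function(len, basic) {
  if (len < 1L) return(character(0))
  sample(c(.UNSTRUCTURED_POOL, basic), len, replace = TRUE)
}

#' Generate one designed amphipathic peptide
#'
#' Places residues on a 100-degree-per-residue helical wheel: positions
#' falling inside the hydrophobic arc draw from \{L, I, V, F, A\}, the
#' remaining positions draw the basic residue (probability 0.5) or a polar
#' residue from \{S, T, N, Q, G\}. Acidic residues are excluded. The
#' designed (ground-truth) helix span is the whole sequence.
#'
#' @param length peptide length, at least 9 residues
#' @param arc hydrophobic-face width, degrees (in (60, 300))
#' @param basic_residue \code{"K"} or \code{"R"}
#' @param seed optional seed; the same seed yields the identical sequence
#' @param id peptide id
#' @return a one-peptide \code{PeptideSet}; the designed span is
#'   \code{attr(, "designed_span")} = c(1, length)
#' @examples
#' makeAmphipathicPeptide(18, seed = 7)
#' @export
makeAmphipathicPeptide <- function(length, arc = 180, basic_residue = "K",
                                   seed = NULL, id = "amphipathic") {
  length <- as.integer(length)
  if (length < 9L) stop("length must be at least 9 residues")
  if (arc <= 60 || arc >= 300) stop("arc must lie in (60, 300) degrees")
  seq <- withSeed(seed, paste(.sampleHelix(length, arc, basic_residue),
                              collapse = ""))
  out <- PeptideSet(stats::setNames(seq, id), role = "OTHER",
                    helix_start = 1L, helix_end = length,
                    name = "designed amphipathic peptide")
  attr(out, "designed_span") <- c(1L, length)
  out
}

.generateOne <- function(spec, id) {
  L <- max(15L, as.integer(round(stats::rnorm(1, spec$length_mean,
                                              spec$length_sd))))
  basic <- spec$basic_residue
  if (spec$class_name == "RANDOM") {
    res <- sample(.RANDOM_POOL, L, replace = TRUE)
    helix <- c(NA_integer_, NA_integer_)
    upstream <- NA_integer_
  } else {
    upstream <- if (spec$upstream_mean > 0)
      max(0L, min(L - 12L, as.integer(round(
        stats::rnorm(1, spec$upstream_mean, spec$upstream_sd)))))
    else 0L
    helix_len <- max(9L, as.integer(round((L - upstream) * spec$helix_cover)))
    helix_len <- min(helix_len, L - upstream)
    tail_len <- L - upstream - helix_len
    res <- c(.sampleUnstructured(upstream, basic),
             .sampleHelix(helix_len, spec$helix_arc, basic),
             .sampleUnstructured(tail_len, basic))
    helix <- c(upstream + 1L, upstream + helix_len)
  }
  # sprinkle acidic residues at the target rate
  acid <- stats::runif(L) < spec$acidic_rate
  if (any(acid)) res[acid] <- sample(c("D", "E"), sum(acid), replace = TRUE)
  list(seq = paste(res, collapse = ""), length = L,
       helix_start = helix[1L], helix_end = helix[2L], upstream = upstream)
}

#' Generate labelled synthetic peptide datasets
#'
#' Builds one \code{PeptideSet} per \code{\link{generatorSpec}}, together
#' with a ground-truth table recording each peptide's class, designed helix
#' span and designed upstream (unstructured prefix) length. The dataset is
#' a pure function of the specs: each class is generated under its own
#' seed, so the same specs always reproduce the same peptides.
#'
#' @param specs a \code{generatorSpec} or list of them
#' @return list with elements \code{peptides} (named list of
#'   \code{PeptideSet}, one per class) and \code{truth} (data.frame with
#'   columns \code{peptide_id}, \code{class}, \code{length},
#'   \code{helix_start}, \code{helix_end}, \code{upstream_length},
#'   \code{seed})
#' @examples
#' d <- generateLabeledDataset(list(
#'   generatorSpec("MTP_LIKE", n = 5, seed = 1),
#'   generatorSpec("CTP_LIKE", n = 5, seed = 2)))
#' d$truth[1:3, ]
#' @export
generateLabeledDataset <- function(specs) {
  if (inherits(specs, "generatorSpec")) specs <- list(specs)
  sets <- list(); truths <- list()
  for (spec in specs) {
    stopifnot(inherits(spec, "generatorSpec"))
    made <- withSeed(spec$seed,
                     lapply(seq_len(spec$n), function(k)
                       .generateOne(spec, k)))
    ids <- sprintf("%s_s%d_%03d", tolower(spec$class_name), spec$seed,
                   seq_len(spec$n))
    role <- switch(spec$class_name, MTP_LIKE = "mTP", CTP_LIKE = "cTP",
                   HARAMP_LIKE = "HA_RAMP", RANDOM = "RANDOM")
    seqs <- stats::setNames(vapply(made, `[[`, character(1), "seq"), ids)
    hs <- vapply(made, `[[`, integer(1), "helix_start")
    he <- vapply(made, `[[`, integer(1), "helix_end")
    sets[[spec$class_name]] <- c(
      sets[[spec$class_name]] %||% NULL,
      list(PeptideSet(seqs, role = role, helix_start = hs, helix_end = he,
                      name = spec$class_name,
                      provenance = paste0("synthetic, seed ", spec$seed))))
    truths[[length(truths) + 1L]] <- data.frame(
      peptide_id = ids, class = spec$class_name,
      length = vapply(made, `[[`, integer(1), "length"),
      helix_start = hs, helix_end = he,
      upstream_length = vapply(made, `[[`, integer(1), "upstream"),
      seed = spec$seed, stringsAsFactors = FALSE)
  }
  peptides <- lapply(sets, function(lst) if (length(lst) == 1L) lst[[1L]]
                     else do.call(c, lst))
  list(peptides = peptides, truth = do.call(rbind, truths))
}
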