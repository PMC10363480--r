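#' @include AllGenerics.R
NULL

#' Construct a PeptideSet
#'
#' @param sequences named character vector of amino-acid sequences (names
#'   are the peptide ids), or an \code{AAStringSet}
#' @param role peptide role(s), recycled; one of \code{HA_RAMP}, \code{mTP},
#'   \code{cTP}, \code{RANDOM}, \code{CONSTRUCT}, \code{ELEMENT},
#'   \code{OTHER}
#' @param cleavage optional integer cleavage-site index(es); NA when absent
#' @param family optional family label(s)
#' @param helix_start,helix_end optional annotated helix span(s), used for
#'   TP records whose helix position is known independently of prediction
#' @param name,provenance set-level metadata
#' @return a \linkS4class{PeptideSet}
#' @examples
#' ps <- PeptideSet(c(p1 = "GIGKFLKS"), role = "HA_RAMP")
#' peptideIds(ps)
#' @export
PeptideSet <- function(sequences, role = "OTHER", cleavage = NA_integer_,
                       family = NA_character_, helix_start = NA_integer_,
                       helix_end = NA_integer_, name = "",
                       provenance = "") {
  if (is.character(sequences)) {
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named by peptide id")
    sequences <- Biostrings::AAStringSet(toupper(sequences))
    names(sequences) <- ids
  }
  n <- length(sequences)
  meta <- S4Vectors::DataFrame(
    role = rep_len(as.character(role), n),
    cleavage = rep_len(as.integer(cleavage), n),
    family = rep_len(as.character(family), n),
    helix_start = rep_len(as.integer(helix_start), n),
    helix_end = rep_len(as.integer(helix_end), n)
  )
  new("PeptideSet", sequences = sequences, meta = meta,
      setName = name, provenance = provenance)
}

#' @rdname PeptideSet-class
#' @export
setMethod("peptideIds", "PeptideSet", function(x) names(x@sequences))

#' @rdname PeptideSet-class
#' @export
setMethod("aaSequences", "PeptideSet", function(x) {
  stats::setNames(as.character(x@sequences), names(x@sequences))
})

#' @rdname PeptideSet-class
#' @export
setMethod("peptideRoles", "PeptideSet", function(x) {
  stats::setNames(x@meta$role, names(x@sequences))
})

#' @rdname PeptideSet-class
#' @export
setMethod("cleavageIndex", "PeptideSet", function(x) {
  stats::setNames(x@meta$cleavage, names(x@sequences))
})

#' @rdname PeptideSet-class
#' @export
setMethod("peptideFamilies", "PeptideSet", function(x) {
  stats::setNames(x@meta$family, names(x@sequences))
})

#' @rdname PeptideSet-class
#' @export
setMethod("helixSpan", "PeptideSet", function(x) {
  data.frame(peptide_id = names(x@sequences),
             helix_start = x@meta$helix_start,
             helix_end = x@meta$helix_end)
})

#' @rdname PeptideSet-class
#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @rdname PeptideSet-class
#' @export
setMethod("names", "PeptideSet", function(x) names(x@sequences))

#' @rdname PeptideSet-class
#' @param i index, id or logical vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, names(x@sequences))
    if (anyNA(idx))
      stop("unknown peptide id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  initialize(x, sequences = x@sequences[i], meta = x@meta[i, , drop = FALSE])
})

#' @rdname PeptideSet-class
#' @export
setMethod("show", "PeptideSet", function(object) {
  cat("PeptideSet", if (nzchar(object@setName)) sQuote(object@setName) else "",
      "with", length(object), "peptide(s)\n")
  if (length(object)) {
    tab <- table(object@meta$role)
    cat("  roles:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
    w <- Biostrings::width(object@sequences)
    cat("  lengths:", min(w), "-", max(w), "residues\n")
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  invisible(object)
})

#' Combine PeptideSets
#'
#' @param x,... \code{PeptideSet} objects to concatenate; ids must stay
#'   unique across the result
#' @return a \code{PeptideSet}
#' @export
setMethod("c", "PeptideSet", function(x, ...) {
  rest <- list(...)
  seqs <- do.call(c, c(list(x@sequences), lapply(rest, slot, "sequences")))
  meta <- do.call(rbind, c(list(x@meta), lapply(rest, slot, "meta")))
  new("PeptideSet", sequences = seqs, meta = meta,
      setName = x@setName, provenance = x@provenance)
})

## ---------------------------------------------------------------- FASTA I/O

# Header grammar: ">id key=value key=value ...". Known keys: role, cleavage,
# family, helix (as "start-end"). Unknown keys are ignored with a warning.
.parseHeader <- function(header) {
  tokens <- strsplit(trimws(header), "\\s+")[[1]]
  id <- tokens[1L]
  out <- list(id = id, role = "OTHER", cleavage = NA_integer_,
              family = NA_character_, helix_start = NA_integer_,
              helix_end = NA_integer_)
  for (tok in tokens[-1L]) {
    if (!grepl("=", tok, fixed = TRUE)) {
      warning("record '", id, "': ignoring header token '", tok, "'",
              call. = FALSE)
      next
    }
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    key <- kv[1L]; val <- paste(kv[-1L], collapse = "=")
    switch(key,
      role = { out$role <- val },
      cleavage = { out$cleavage <- as.integer(val) },
      family = { out$family <- val },
      helix = {
        se <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
        out$helix_start <- se[1L]; out$helix_end <- se[2L]
      },
      warning("record '", id, "': ignoring unknown header key '", key, "'",
              call. = FALSE)
    )
  }
  out
}

#' Read and write peptide FASTA files
#'
#' \code{readPeptides} parses a FASTA file of amino-acid sequences into a
#' \linkS4class{PeptideSet}. Header lines may carry space-separated
#' \code{key=value} tokens after the id: \code{role=}, \code{cleavage=},
#' \code{family=} and \code{helix=start-end}; unknown keys are ignored with
#' a warning. Sequences are uppercased; a character outside the 20 standard
#' residues is an error naming the record and position; duplicate ids are
#' an error. \code{writePeptides} is the inverse: re-reading a written file
#' reproduces the set (byte-identical up to line wrapping).
#'
#' @param path file path
#' @param name,provenance set-level metadata for the returned set
#' @return \code{readPeptides}: a \code{PeptideSet}; \code{writePeptides}:
#'   the path, invisibly.
#' @examples
#' fa <- system.file("extdata", "fig1_peptides_synthetic.fasta",
#'                   package = "chimeraTP")
#' peps <- readPeptides(fa)
#' table(peptideRoles(peps))
#' @export
readPeptides <- function(path, name = basename(path), provenance = path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readAAStringSet(path)
  heads <- lapply(names(raw), .parseHeader)
  ids <- vapply(heads, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate peptide id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) .checkAlphabet(seqs[i], ids[i])
  PeptideSet(stats::setNames(seqs, ids),
             role = vapply(heads, `[[`, character(1), "role"),
             cleavage = vapply(heads, `[[`, integer(1), "cleavage"),
             family = vapply(heads, `[[`, character(1), "family"),
             helix_start = vapply(heads, `[[`, integer(1), "helix_start"),
             helix_end = vapply(heads, `[[`, integer(1), "helix_end"),
             name = name, provenance = provenance)
}

#' @rdname readPeptides
#' @param x a \code{PeptideSet}
#' @export
writePeptides <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  m <- x@meta
  heads <- vapply(seq_len(length(x)), function(i) {
    h <- names(x@sequences)[i]
    if (!is.na(m$role[i]) && m$role[i] != "OTHER")
      h <- paste0(h, " role=", m$role[i])
    if (!is.na(m$cleavage[i])) h <- paste0(h, " cleavage=", m$cleavage[i])
    if (!is.na(m$family[i])) h <- paste0(h, " family=", m$family[i])
    if (!is.na(m$helix_start[i]))
      h <- paste0(h, " helix=", m$helix_start[i], "-", m$helix_end[i])
    h
  }, character(1))
  out <- x@sequences
  names(out) <- heads
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

## --------------------------------------------------- K/R substitution

#' Swap the basic residues of peptides
#'
#' Replaces every lysine by arginine (\code{K_TO_R}) or every arginine by
#' lysine (\code{R_TO_K}) in each peptide of the set, leaving all other
#' residues and the length unchanged. This emulates the systematic
#' basic-residue exchange used to probe the functional split between
#' K-rich antimicrobial peptides and R-rich targeting peptides. Ids gain a
#' \code{_R} or \code{_K} suffix; peptides lacking the source residue are
#' returned unchanged apart from the suffix.
#'
#' @param x a \code{PeptideSet}
#' @param direction \code{"K_TO_R"} or \code{"R_TO_K"}
#' @return a \code{PeptideSet} of equal length
#' @examples
#' ps <- PeptideSet(c(p = "GIGKFLK"))
#' aaSequences(substituteBasic(ps, "K_TO_R"))
#' @rdname substituteBasic
#' @export
setMethod("substituteBasic", "PeptideSet", function(x, direction = c("K_TO_R", "R_TO_K")) {
  direction <- match.arg(direction)
  from <- if (direction == "K_TO_R") "K" else "R"
  to <- if (direction == "K_TO_R") "R" else "K"
  seqs <- chartr(from, to, as.character(x@sequences))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- paste0(names(x@sequences), "_", to)
  initialize(x, sequences = out)
})

## --------------------------------------------------- element extraction

#' Extract targeting-peptide elements
#'
#' \code{extractNElement} returns the first \code{n} residues of each
#' peptide (default 15, the length of the cTP N-terminal element upstream
#' of the helix). \code{extractCElement} returns the cleavage-site region:
#' residues from \code{upstream} positions before the cleavage site through
#' \code{downstream} positions after it (defaults 10 and 23, so a 33-residue
#' element whose own cleavage index is \code{upstream}). Peptides shorter
#' than requested, or lacking a cleavage index, are an error; no padding is
#' performed.
#'
#' @param x a \code{PeptideSet}
#' @param n number of N-terminal residues
#' @param upstream,downstream residues kept before/after the cleavage site
#' @return a \code{PeptideSet} of \code{ELEMENT}-role peptides
#' @examples
#' tp <- PeptideSet(c(tp = strrep("ACDEFGHIKL", 7)), role = "cTP",
#'                  cleavage = 36)
#' nchar(aaSequences(extractCElement(tp)))  # 33
#' @rdname extractNElement
#' @export
setMethod("extractNElement", "PeptideSet", function(x, n = 15L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  w <- Biostrings::width(x@sequences)
  short <- w < n
  if (any(short))
    stop("peptide(s) shorter than n = ", n, ": ",
         paste(names(x@sequences)[short], collapse = ", "))
  seqs <- substr(as.character(x@sequences), 1L, n)
  PeptideSet(stats::setNames(seqs, paste0(names(x@sequences), "_N", n)),
             role = "ELEMENT", name = x@setName, provenance = x@provenance)
})

#' @rdname extractNElement
#' @export
setMethod("extractCElement", "PeptideSet", function(x, upstream = 10L, downstream = 23L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  cl <- x@meta$cleavage
  ids <- names(x@sequences)
  if (anyNA(cl))
    stop("cleavage index missing for: ", paste(ids[is.na(cl)], collapse = ", "))
  w <- Biostrings::width(x@sequences)
  if (any(cl < upstream))
    stop("cleavage index < upstream for: ",
         paste(ids[cl < upstream], collapse = ", "),
         " (need at least ", upstream, " residues before the site)")
  over <- w < cl + downstream
  if (any(over)) {
    i <- which(over)[1L]
    stop("peptide '", ids[i], "' has only ", w[i] - cl[i],
         " residue(s) downstream of the cleavage site; ", downstream,
         " requested")
  }
  seqs <- substr(as.character(x@sequences), cl - upstream + 1L, cl + downstream)
  PeptideSet(stats::setNames(seqs, paste0(ids, "_C")),
             role = "ELEMENT", cleavage = upstream,
             name = x@setName, provenance = x@provenance)
})

## --------------------------------------------------- construct grammar

#' Canonical core codes and grid coordinates
#'
#' \code{canonicalCores} lists the 13 HA-RAMP codes in grid-column order
#' (columns a-m); \code{gridColumnMap} maps all grid columns a-s to their
#' core tokens (n-o the random peptides, p = CH, q = MH, r = \code{-},
#' s = AA); \code{constructRowTable} gives the fixed row semantics: each
#' row letter A-L is one combination of basic variant, N-element and
#' C-element.
#'
#' @return \code{canonicalCores}: character vector; \code{gridColumnMap}:
#'   named character vector; \code{constructRowTable}: data.frame with
#'   columns \code{row}, \code{basic_variant}, \code{n_element},
#'   \code{c_element}.
#' @export
canonicalCores <- function() {
  c("B2I", "MII", "R2G", "DS4", "DDM", "B1E", "CP3",
    "S1D", "E1S", "LCA", "SIM", "B15", "EHF")
}

#' @rdname canonicalCores
#' @export
gridColumnMap <- function() {
  stats::setNames(c(canonicalCores(), "RP1", "RP2", "CH", "MH", "-", "AA"),
                  letters[1:19])
}

#' @rdname canonicalCores
#' @export
constructRowTable <- function() {
  data.frame(
    row = LETTERS[1:12],
    basic_variant = rep(c("K", "R"), 6),
    n_element = rep(c("NONE", "NONE", "NONE", "CTP_N", "CTP_N", "CTP_N"),
                    each = 2),
    c_element = rep(c("NONE", "MTP_C", "CTP_C"), each = 2, times = 2)[1:12],
    stringsAsFactors = FALSE
  )
}

.rowFor <- function(basic_variant, n_element, c_element) {
  tab <- constructRowTable()
  hit <- tab$basic_variant == basic_variant & tab$n_element == n_element &
    tab$c_element == c_element
  if (any(hit)) tab$row[hit] else NA_character_
}

.columnFor <- function(core_id) {
  map <- gridColumnMap()
  hit <- match(core_id, map)
  if (is.na(hit)) NA_character_ else names(map)[hit]
}

#' Parse and format construct codes
#'
#' Construct codes follow the ASCII grammar
#' \code{["^c"] CORE ["_K"|"_R"] ["^c"|"^m"]}: a leading \code{^c} adds the
#' cTP N-terminal element, the \code{_K}/\code{_R} subscript names the
#' basic-residue variant, and a trailing \code{^c}/\code{^m} adds the cTP
#' or mTP C-terminal element. \code{CORE} is one of the 13 HA-RAMP codes,
#' \code{RP1}, \code{RP2}, \code{CH}, \code{MH}, \code{AA} or \code{-}.
#' \code{formatConstructCode} is the exact inverse on canonical codes.
#'
#' @param code a construct code such as \code{"^cB2I_R^m"}
#' @param cores valid core tokens
#' @return \code{parseConstructCode}: a \linkS4class{ConstructSpec};
#'   \code{formatConstructCode}: a string.
#' @examples
#' spec <- parseConstructCode("^cB2I_R^m")
#' formatConstructCode(spec)
#' @export
parseConstructCode <- function(code, cores = unname(gridColumnMap())) {
  stopifnot(is.character(code), length(code) == 1L)
  rest <- code
  n_element <- "NONE"
  if (startsWith(rest, "^c")) {
    # leading ^c is the N-element only if what follows still contains a core
    body <- substring(rest, 3L)
    if (nzchar(body)) { n_element <- "CTP_N"; rest <- body }
  }
  c_element <- "NONE"
  if (grepl("\\^c$", rest) && nchar(rest) > 2L) {
    c_element <- "CTP_C"; rest <- substr(rest, 1L, nchar(rest) - 2L)
  } else if (grepl("\\^m$", rest)) {
    c_element <- "MTP_C"; rest <- substr(rest, 1L, nchar(rest) - 2L)
  }
  basic_variant <- "NATIVE"
  if (grepl("_K$", rest)) {
    basic_variant <- "K"; rest <- substr(rest, 1L, nchar(rest) - 2L)
  } else if (grepl("_R$", rest)) {
    basic_variant <- "R"; rest <- substr(rest, 1L, nchar(rest) - 2L)
  }
  if (!(rest %in% cores))
    stop("malformed construct code '", code, "': unknown core token '",
         rest, "'")
  new("ConstructSpec", core_id = rest, basic_variant = basic_variant,
      n_element = n_element, c_element = c_element,
      row = if (basic_variant == "NATIVE") NA_character_ else
        .rowFor(basic_variant, n_element, c_element),
      column = .columnFor(rest))
}

#' @rdname parseConstructCode
#' @param spec a \code{ConstructSpec}
#' @export
formatConstructCode <- function(spec) {
  stopifnot(is(spec, "ConstructSpec"))
  paste0(if (spec@n_element == "CTP_N") "^c" else "",
         spec@core_id,
         switch(spec@basic_variant, K = "_K", R = "_R", ""),
         switch(spec@c_element, CTP_C = "^c", MTP_C = "^m", ""))
}

#' @rdname ConstructSpec-class
#' @export
setMethod("show", "ConstructSpec", function(object) {
  cat("ConstructSpec", formatConstructCode(object),
      sprintf("[core=%s variant=%s n=%s c=%s row=%s column=%s]\n",
              object@core_id, object@basic_variant, object@n_element,
              object@c_element, object@row, object@column))
  invisible(object)
})

## --------------------------------------------------- assembly

#' Build the TP element library from a peptide library
#'
#' Derives the reusable construct elements from a library containing the
#' reference cTP and mTP records (with cleavage indices and annotated helix
#' spans): \code{CTP_N} (first 15 residues of the cTP), \code{CTP_C} and
#' \code{MTP_C} (cleavage-site regions, -10/+23 around the site), and the
#' bare helical fragments \code{CH} (cTP helix) and \code{MH} (mTP helix,
#' its N-terminal part up to the start of the C-element).
#'
#' @param library a \code{PeptideSet} containing \code{ctp_id} and
#'   \code{mtp_id}
#' @param ctp_id,mtp_id ids of the reference cTP and mTP records
#' @return a \code{PeptideSet} with ids \code{CTP_N}, \code{CTP_C},
#'   \code{MTP_C}, \code{CH}, \code{MH}
#' @export
elementLibrary <- function(library, ctp_id = "RCA1_cTP", mtp_id = "CAG2_mTP") {
  stopifnot(is(library, "PeptideSet"))
  ids <- peptideIds(library)
  if (!all(c(ctp_id, mtp_id) %in% ids))
    stop("library must contain records '", ctp_id, "' and '", mtp_id, "'")
  ctp <- library[ctp_id]; mtp <- library[mtp_id]
  hs <- helixSpan(ctp); ms <- helixSpan(mtp)
  if (anyNA(hs$helix_start) || anyNA(ms$helix_start))
    stop("reference TP records need annotated helix spans (helix= header key)")
  ctp_seq <- aaSequences(ctp)[[1]]
  mtp_seq <- aaSequences(mtp)[[1]]
  mtp_cl <- cleavageIndex(mtp)[[1]]
  seqs <- c(
    CTP_N = substr(ctp_seq, 1L, 15L),
    CTP_C = aaSequences(extractCElement(ctp))[[1]],
    MTP_C = aaSequences(extractCElement(mtp))[[1]],
    CH = substr(ctp_seq, hs$helix_start, hs$helix_end),
    MH = substr(mtp_seq, ms$helix_start, min(ms$helix_end, mtp_cl - 10L))
  )
  PeptideSet(seqs, role = "ELEMENT",
             cleavage = c(NA, 10L, 10L, NA, NA),
             name = "TP elements", provenance = library@provenance)
}

#' Assemble a chimeric construct
#'
#' Builds the peptide a \linkS4class{ConstructSpec} describes: the core
#' (after basic-residue substitution when the requested variant differs
#' from the native sequence) is concatenated, without linkers, with the cTP
#' N-terminal element and/or a C-terminal TP element. Special cores:
#' \code{CH}/\code{MH} are the TP helical fragments from \code{elements};
#' \code{AA} is a poly-alanine of the same length as \code{CH}; \code{-}
#' concatenates the flanking elements directly. When a C-element is
#' present, the construct's cleavage index is 10 residues before the end of
#' the element's upstream part, i.e. at \code{length - 23}.
#'
#' @param spec a \code{ConstructSpec} (or a construct code string)
#' @param library \code{PeptideSet} holding the core peptides
#' @param elements \code{PeptideSet} from \code{\link{elementLibrary}}
#' @return a single-peptide \code{PeptideSet} with role \code{CONSTRUCT},
#'   id the canonical construct code
#' @examples
#' lib <- readPeptides(system.file("extdata", "fig1_peptides_synthetic.fasta",
#'                                 package = "chimeraTP"))
#' els <- elementLibrary(lib)
#' assembleConstruct("^cB2I_R^m", lib, els)
#' @export
assembleConstruct <- function(spec, library, elements = elementLibrary(library)) {
  if (is.character(spec)) spec <- parseConstructCode(spec)
  stopifnot(is(spec, "ConstructSpec"), is(library, "PeptideSet"))
  el_ids <- peptideIds(elements)
  core_id <- spec@core_id
  core <- if (core_id == "-") {
    ""
  } else if (core_id == "AA") {
    if (!("CH" %in% el_ids))
      stop("AA core needs the CH element to fix the poly-alanine length")
    strrep("A", nchar(aaSequences(elements)[["CH"]]))
  } else if (core_id %in% el_ids) {
    aaSequences(elements)[[core_id]]
  } else if (core_id %in% peptideIds(library)) {
    aaSequences(library)[[core_id]]
  } else {
    stop("unknown core id '", core_id, "'")
  }
  core <- switch(spec@basic_variant,
                 K = chartr("R", "K", core),
                 R = chartr("K", "R", core),
                 core)
  prefix <- if (spec@n_element == "CTP_N") aaSequences(elements)[["CTP_N"]] else ""
  suffix <- switch(spec@c_element,
                   CTP_C = aaSequences(elements)[["CTP_C"]],
                   MTP_C = aaSequences(elements)[["MTP_C"]],
                   "")
  seq <- paste0(prefix, core, suffix)
  cl <- if (spec@c_element == "NONE") NA_integer_ else
    nchar(prefix) + nchar(core) + 10L
  PeptideSet(stats::setNames(seq, formatConstructCode(spec)),
             role = "CONSTRUCT", cleavage = cl,
             name = library@setName, provenance = library@provenance)
}
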