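#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' Extracts one C-alpha record per (chain, residue): among alternate
#' locations the highest-occupancy one is kept (first in file on ties);
#' residues with insertion codes are excluded from the mature-numbering
#' mapping. Author residue numbers are converted to mature-protein numbering
#' by an optional per-chain offset (`mature = author + offset`), the default
#' offset of 0 meaning the two numbering schemes coincide.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param offsets Named numeric vector of per-chain numbering offsets, e.g.
#'   `c(A = 0, B = -645)`; chains not named get offset 0.
#' @param structure_id Identifier stored with the model (defaults to the
#'   file name).
#'
#' @return An `xl_structure`: a tibble with columns `chain`, `resno`
#'   (mature numbering), `resno_author`, `residue_type` (one-letter code),
#'   `x`, `y`, `z`, with attribute `structure_id`.
#' @export
read_structure <- function(path, offsets = NULL, structure_id = NULL) {
  if (!file.exists(path)) {
    stop("Structure file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, verbose = FALSE)
    },
    error = function(e) {
      stop("Could not parse structure file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  atoms <- tibble::as_tibble(pdb$atom)
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", ]
  if (nrow(ca) == 0) {
    stop("No C-alpha atoms found in ", path, call. = FALSE)
  }
  # drop insertion-code residues from the mature mapping
  ca <- ca[is.na(ca$insert) | ca$insert == "" | ca$insert == "?", ]
  # highest-occupancy altloc, first in file on ties
  occ <- ca$o
  occ[is.na(occ)] <- 1
  ord <- order(ca$chain, ca$resno, -occ)
  ca <- ca[ord, ]
  ca <- ca[!duplicated(ca[, c("chain", "resno")]), ]
  off <- rep(0, nrow(ca))
  if (!is.null(offsets)) {
    hit <- match(ca$chain, names(offsets))
    off <- ifelse(is.na(hit), 0, offsets[hit])
  }
  out <- tibble::tibble(
    chain = ca$chain,
    resno = as.integer(ca$resno + off),
    resno_author = as.integer(ca$resno),
    residue_type = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z
  )
  out <- out[order(out$resno), ]
  if (anyDuplicated(out$resno)) {
    stop("Duplicate mature residue numbers after applying offsets; ",
         "check the per-chain offsets.", call. = FALSE)
  }
  attr(out, "structure_id") <- structure_id %||% basename(path)
  class(out) <- c("xl_structure", class(out))
  out
}

#' Build a structure model from a coordinate table
#'
#' For synthetic systems: wraps a tibble with `resno`, `x`, `y`, `z` (and
#' optionally `chain`, `residue_type`) as an `xl_structure`.
#'
#' @param coords Coordinate data frame.
#' @param structure_id Identifier.
#' @return An `xl_structure`.
#' @export
as_structure <- function(coords, structure_id = "synthetic") {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("resno", "x", "y", "z") %in% names(coords)))
  if (!"chain" %in% names(coords)) coords$chain <- "A"
  if (!"residue_type" %in% names(coords)) coords$residue_type <- "X"
  out <- coords[order(coords$resno),
                c("chain", "resno", "x", "y", "z", "residue_type")]
  attr(out, "structure_id") <- structure_id
  class(out) <- c("xl_structure", class(out))
  out
}

#' C-alpha to C-alpha distance between two residues
#'
#' @param s An `xl_structure`.
#' @param a,b Mature residue numbers (vectors recycle).
#' @param substitute If `TRUE`, an unresolved residue is replaced by the
#'   nearest resolved residue in sequence ([nearest_resolved()]); if `FALSE`,
#'   unresolved residues raise an error.
#' @return Euclidean distance(s) in Angstrom.
#' @export
ca_distance <- function(s, a, b, substitute = FALSE) {
  idx <- function(pos) {
    i <- match(pos, s$resno)
    if (any(is.na(i))) {
      if (!substitute) {
        stop("Residue(s) ", paste(pos[is.na(i)], collapse = ", "),
             " not resolved in structure ", attr(s, "structure_id"),
             " (set substitute = TRUE to use the nearest resolved residue).",
             call. = FALSE)
      }
      pos[is.na(i)] <- vapply(pos[is.na(i)],
                              function(p) nearest_resolved(s, p), numeric(1))
      i <- match(pos, s$resno)
    }
    i
  }
  ia <- idx(a)
  ib <- idx(b)
  sqrt((s$x[ia] - s$x[ib])^2 + (s$y[ia] - s$y[ib])^2 +
         (s$z[ia] - s$z[ib])^2)
}

#' Nearest resolved residue in sequence
#'
#' Returns `pos` itself when resolved, otherwise the resolved residue number
#' minimizing the sequence distance, ties broken toward the lower number.
#'
#' @param s An `xl_structure`.
#' @param pos A mature residue number.
#' @return A resolved residue number.
#' @export
nearest_resolved <- function(s, pos) {
  if (nrow(s) == 0) stop("Structure has no resolved residues.", call. = FALSE)
  if (pos %in% s$resno) return(pos)
  d <- abs(s$resno - pos)
  cand <- s$resno[d == min(d)]
  min(cand)
}

#' Assess cross-links against a crystal structure
#'
#' Measures each link's C-alpha distance, compares it with the theoretical
#' cross-linkable limit from [max_link_distance()], and flags violations
#' (`distance > limit`). Unresolved residues are substituted by the nearest
#' resolved residue in sequence, and the substitutions recorded.
#'
#' @param s An `xl_structure`.
#' @param links Link data frame with `res_a`, `res_b` and optionally
#'   `type_a`, `type_b` (one-letter reactive residue types). Missing types
#'   are looked up from the structure at the requested positions; links whose
#'   types are not reactive for the linker get `limit = NA`.
#' @param linker A [linker_spec()] (default BS3).
#' @param substitute Substitute unresolved residues (default `TRUE`).
#' @return A tibble with per link: `link_id`, `res_a`, `res_b`, `used_a`,
#'   `used_b` (positions actually measured), `substituted`, `distance`,
#'   `limit`, `violated`.
#' @export
assess_links <- function(s, links, linker = default_bs3_linker(),
                         substitute = TRUE) {
  links <- normalize_links(links)
  n <- nrow(links)
  used_a <- used_b <- integer(n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    used_a[i] <- if (substitute) {
      nearest_resolved(s, links$res_a[i])
    } else {
      links$res_a[i]
    }
    used_b[i] <- if (substitute) {
      nearest_resolved(s, links$res_b[i])
    } else {
      links$res_b[i]
    }
    dist[i] <- ca_distance(s, used_a[i], used_b[i], substitute = FALSE)
  }
  type_of <- function(col, pos) {
    if (col %in% names(links)) {
      as.character(links[[col]])
    } else {
      s$residue_type[match(pos, s$resno)]
    }
  }
  ta <- type_of("type_a", links$res_a)
  tb <- type_of("type_b", links$res_b)
  limit <- rep(NA_real_, n)
  reactive <- names(linker$reactive_residues)
  ok <- !is.na(ta) & !is.na(tb) & ta %in% reactive & tb %in% reactive
  limit[ok] <- mapply(function(a, b) max_link_distance(linker, a, b),
                      ta[ok], tb[ok])
  tibble::tibble(
    link_id = links$link_id,
    res_a = links$res_a, res_b = links$res_b,
    used_a = used_a, used_b = used_b,
    substituted = used_a != links$res_a | used_b != links$res_b,
    type_a = ta, type_b = tb,
    distance = dist, limit = limit,
    violated = ifelse(is.na(limit), NA, dist > limit)
  )
}

#' Export link assessments as a PyMOL command script
#'
#' Writes a deterministic `.pml`-dialect script drawing every assessed link
#' as a distance object between the C-alpha atoms of the (possibly
#' substituted) residues, colored by category when categories are given.
#'
#' @param s An `xl_structure` (used for chain lookup).
#' @param assessments Output of [assess_links()].
#' @param categories Optional character vector (recycled) of categories per
#'   link; recognized values get the conventional colors (mutual gray,
#'   unique/enriched in condition 1 blue/cyan, in condition 2
#'   green/forest).
#' @param object Name of the loaded structure object in the viewer.
#' @return The script as a single character string (invisibly returns it;
#'   write with `writeLines`).
#' @export
export_visualization <- function(s, assessments, categories = NULL,
                                 object = "structure") {
  colmap <- c(unique_1 = "blue", enriched_1 = "cyan", mutual = "gray50",
              enriched_2 = "forest", unique_2 = "green")
  n <- nrow(assessments)
  if (is.null(categories)) categories <- rep("mutual", n)
  categories <- rep_len(as.character(categories), n)
  ord <- order(assessments$link_id)
  lines <- c(
    "# cross-link visualization script (PyMOL dialect)",
    "hide labels"
  )
  chain_of <- function(pos) {
    ch <- s$chain[match(pos, s$resno)]
    ifelse(is.na(ch), "A", ch)
  }
  for (i in ord) {
    nm <- paste0("xl_", gsub("-", "_", assessments$link_id[i]))
    sel_a <- sprintf("(%s and chain %s and resi %d and name CA)", object,
                     chain_of(assessments$used_a[i]), assessments$used_a[i])
    sel_b <- sprintf("(%s and chain %s and resi %d and name CA)", object,
                     chain_of(assessments$used_b[i]), assessments$used_b[i])
    col <- colmap[categories[i]]
    if (is.na(col)) col <- "gray50"
    lines <- c(lines,
               sprintf("distance %s, %s, %s", nm, sel_a, sel_b),
               sprintf("color %s, %s", col, nm))
  }
  lines <- c(lines, "set dash_gap, 0")
  paste(lines, collapse = "\n")
}

#' Write an assessment table as TSV
#'
#' @param assessments Output of [assess_links()].
#' @param path Output path.
#' @export
write_assessment_tsv <- function(assessments, path) {
  readr::write_tsv(assessments, path, progress = FALSE)
  invisible(path)
}
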