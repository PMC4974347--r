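#' Domain annotation for a multi-domain protein
#'
#' Describes a (possibly two-chain) protein in mature-protein numbering:
#' chain residue ranges and named domains, each covering one or more
#' non-overlapping residue segments. Complement C3, for example, spans
#' residues 1-645 (beta chain) and 650-1641 (alpha chain), with domains
#' ANA, MG1-MG8, LNK, CUB, TED, C345C, anchor and the alpha-NT segment.
#'
#' @param protein_id Protein identifier.
#' @param chains Data frame with columns `chain_id`, `first_residue`,
#'   `last_residue`; chain ranges must be disjoint.
#' @param domains Data frame with columns `name`, `start`, `end`: one row per
#'   segment (a domain may have several segments). Segments of different
#'   domains must not overlap.
#'
#' @return An object of class `domain_annotation`.
#' @seealso [read_domain_annotation()], [annotate_residue()]
#' @export
domain_annotation <- function(protein_id, chains, domains) {
  chains <- tibble::as_tibble(chains)
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("chain_id", "first_residue", "last_residue") %in%
                  names(chains)),
            all(c("name", "start", "end") %in% names(domains)))
  if (any(domains$start > domains$end)) {
    stop("Domain segments must have start <= end.", call. = FALSE)
  }
  if (any(chains$first_residue > chains$last_residue)) {
    stop("Chain ranges must have first_residue <= last_residue.",
         call. = FALSE)
  }
  # chain ranges disjoint
  ord <- order(chains$first_residue)
  if (nrow(chains) > 1 &&
      any(chains$first_residue[ord][-1] <=
            chains$last_residue[ord][-nrow(chains)])) {
    stop("Chain residue ranges overlap.", call. = FALSE)
  }
  # every residue in at most one domain
  covered <- unlist(Map(seq, domains$start, domains$end))
  if (anyDuplicated(covered)) {
    dup <- covered[duplicated(covered)][1]
    stop(sprintf("Residue %d is covered by more than one domain segment.",
                 dup), call. = FALSE)
  }
  # segments within a domain ascending
  domains <- dplyr::arrange(domains, .data$name, .data$start)
  structure(
    list(protein_id = protein_id, chains = chains, domains = domains),
    class = "domain_annotation"
  )
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("<domain_annotation> ", x$protein_id, ": ",
      nrow(x$chains), " chain(s), ",
      length(unique(x$domains$name)), " domains\n", sep = "")
  invisible(x)
}

#' Read a domain annotation from a YAML config
#'
#' The config has `protein_id`, a `chains` list (`chain_id`, `first_residue`,
#' `last_residue`) and a `domains` list (`name`, `segments` of `[start, end]`
#' pairs). The package ships `c3_domains.yaml`, a reconstructed (approximate,
#' figure-level) annotation of complement C3; see
#' `system.file("extdata", "c3_domains.yaml", package = "qclms")`.
#'
#' @param path Path to the YAML file.
#' @return A [domain_annotation()].
#' @export
read_domain_annotation <- function(path) {
  cfg <- yaml::read_yaml(path)
  chains <- dplyr::bind_rows(lapply(cfg$chains, tibble::as_tibble))
  domains <- dplyr::bind_rows(lapply(cfg$domains, function(d) {
    segs <- do.call(rbind, lapply(d$segments, function(s) {
      as.numeric(unlist(s))
    }))
    tibble::tibble(name = d$name, start = segs[, 1], end = segs[, 2])
  }))
  domain_annotation(cfg$protein_id, chains, domains)
}

#' Reconstructed complement C3 domain annotation
#'
#' Convenience loader for the shipped C3 config (mature-protein numbering,
#' beta chain 1-645, alpha chain 650-1641). Domain boundaries are a
#' reconstruction from figure-level information and the crystallographic
#' literature, not an authoritative table; edit the YAML to refine them.
#'
#' @return A [domain_annotation()].
#' @export
c3_domain_annotation <- function() {
  read_domain_annotation(
    system.file("extdata", "c3_domains.yaml", package = "qclms")
  )
}

#' Annotate residue positions with chain and domain labels
#'
#' @param pos Integer vector of 1-based mature-protein residue positions.
#' @param ann A [domain_annotation()].
#'
#' @return A tibble with columns `position`, `chain`, `domain` (`NA` for
#'   positions outside every annotated domain or chain).
#' @examples
#' ann <- c3_domain_annotation()
#' annotate_residue(c(44, 1049, 727), ann)
#' @export
annotate_residue <- function(pos, ann) {
  stopifnot(inherits(ann, "domain_annotation"), all(pos >= 1))
  chain <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(ann$chains))) {
    hit <- pos >= ann$chains$first_residue[i] &
      pos <= ann$chains$last_residue[i]
    chain[hit] <- ann$chains$chain_id[i]
  }
  domain <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(ann$domains))) {
    hit <- pos >= ann$domains$start[i] & pos <= ann$domains$end[i]
    domain[hit] <- ann$domains$name[i]
  }
  tibble::tibble(position = as.integer(pos), chain = chain, domain = domain)
}

#' Canonical unordered cross-link identifiers
#'
#' A cross-link between residues a and b is the same link as between b and a.
#' `normalize_links()` reorders each pair so `res_a <= res_b` (swapping the
#' residue-type columns along with the positions) and adds a canonical
#' `link_id` of the form `"a-b"`. Duplicated identities collapse to one id.
#'
#' @param links Data frame with integer columns `res_a`, `res_b` and
#'   optionally `type_a`, `type_b`.
#' @return The input as a tibble with normalized pair order plus `link_id`.
#' @export
normalize_links <- function(links) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("res_a", "res_b") %in% names(links)))
  swap <- links$res_a > links$res_b
  if (any(swap)) {
    tmp <- links$res_a[swap]
    links$res_a[swap] <- links$res_b[swap]
    links$res_b[swap] <- tmp
    if (all(c("type_a", "type_b") %in% names(links))) {
      tmp <- links$type_a[swap]
      links$type_a[swap] <- links$type_b[swap]
      links$type_b[swap] <- tmp
    }
  }
  links$link_id <- paste0(links$res_a, "-", links$res_b)
  links
}

#' Annotate a link table with domain labels
#'
#' Adds `domain_a`/`domain_b` columns (and the conventional
#' `"44^MG1^-1049^TED^"`-style `link_label`) to a normalized link table.
#'
#' @param links Data frame with `res_a`, `res_b` (normalized via
#'   [normalize_links()] if needed).
#' @param ann A [domain_annotation()].
#' @return The link tibble with `domain_a`, `domain_b`, `link_label`.
#' @export
annotate_links <- function(links, ann) {
  links <- normalize_links(links)
  links$domain_a <- annotate_residue(links$res_a, ann)$domain
  links$domain_b <- annotate_residue(links$res_b, ann)$domain
  lab <- function(pos, dom) {
    ifelse(is.na(dom), as.character(pos), paste0(pos, "^", dom, "^"))
  }
  links$link_label <- paste0(lab(links$res_a, links$domain_a), "-",
                             lab(links$res_b, links$domain_b))
  links
}

#' Read / write cross-link lists
#'
#' Tab-separated link lists with columns `res_a`, `res_b` and optional
#' `type_a`, `type_b`, `class` and domain labels.
#'
#' @param path File path.
#' @return `read_link_table()` returns a normalized link tibble.
#' @export
read_link_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  normalize_links(tbl)
}

#' @param links Link tibble to write.
#' @rdname read_link_table
#' @export
write_link_table <- function(links, path) {
  readr::write_tsv(tibble::as_tibble(links), path, progress = FALSE)
  invisible(path)
}
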