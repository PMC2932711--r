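#' Construct a fly-to-mouse homolog map
#'
#' @param entries Named list: names are fly gene symbols, values are
#'   character vectors of one or more mouse symbols. Many-to-one is
#'   allowed (several fly genes mapping to the same mouse gene).
#' @param synonyms Synonym table applied to the mouse symbols.
#' @return Object of class `homolog_map`: list with `entries` (named list
#'   of canonical mouse symbol vectors) and `synonyms`.
#' @export
homolog_map <- function(entries, synonyms = default_synonyms()) {
  if (!is.list(entries) || is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("`entries` must be a named list keyed by fly gene symbol", call. = FALSE)
  }
  fly <- normalize_symbol(names(entries), synonyms = character(0))
  mapped <- lapply(entries, function(m) {
    m <- canonicalize_symbols(as.character(m), synonyms)
    unique(m)
  })
  if (any(lengths(mapped) == 0)) {
    bad <- fly[lengths(mapped) == 0][1]
    stop(sprintf("fly gene '%s' maps to no mouse symbol", bad), call. = FALSE)
  }
  names(mapped) <- fly
  structure(list(entries = mapped, synonyms = synonyms), class = "homolog_map")
}

#' @export
print.homolog_map <- function(x, ...) {
  n_mouse <- length(unique(symbol_key(unlist(x$entries, use.names = FALSE))))
  cat(sprintf("<homolog_map> %d fly genes -> %d distinct mouse symbols\n",
              length(x$entries), n_mouse))
  invisible(x)
}

#' Read a homolog map from two-column TSV
#'
#' Column 1: fly symbol; column 2: mouse symbol(s), separated by commas or
#' slashes (`Six1/Six2`). Duplicate fly rows are merged with the union of
#' their mouse symbols (a warning is issued). An empty mouse field is a
#' format error.
#'
#' @param path Path to TSV (a header line starting with "fly" is skipped).
#' @inheritParams homolog_map
#' @return A [homolog_map()].
#' @export
read_homolog_map <- function(path, synonyms = default_synonyms()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) && grepl("^fly([_ ]?gene)?\t", tolower(lines[[1]]))) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) stop(sprintf("'%s': no homolog entries", path), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fly <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  mouse_field <- vapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(trimws(p[[2]]))) NA_character_ else trimws(p[[2]])
  }, character(1))
  if (anyNA(mouse_field)) {
    stop(sprintf("'%s': fly gene '%s' has an empty mouse homolog field",
                 path, fly[which(is.na(mouse_field))[1]]), call. = FALSE)
  }
  mouse <- lapply(strsplit(mouse_field, "[,/]"), trimws)
  if (anyDuplicated(tolower(fly))) {
    warning(sprintf("'%s': duplicate fly rows merged with union of mouse symbols", path),
            call. = FALSE)
    keyf <- factor(tolower(fly), levels = unique(tolower(fly)))
    merged <- tapply(mouse, keyf, function(ms) unique(unlist(ms)), simplify = FALSE)
    fly <- fly[!duplicated(tolower(fly))]
    mouse <- unname(merged)
  }
  names(mouse) <- fly
  homolog_map(mouse, synonyms)
}

#' Construct a signed seed-network specification
#'
#' A small literature-curated graph among fly genes: undirected signed
#' edges, no self-edges, no duplicate unordered pairs.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `sign`
#'   (+1/-1), and optionally `provenance` (free-text citation).
#' @param nodes Optional character vector of fly nodes; defaults to the
#'   union of edge endpoints. Isolated nodes may be added here.
#' @return Object of class `seed_network_spec`: list with `fly_nodes` and
#'   `fly_edges` (data frame `gene_a`, `gene_b`, `sign`, `provenance`).
#' @export
seed_network_spec <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("gene_a", "gene_b", "sign")
  if (!all(need %in% names(edges))) {
    stop("`edges` needs columns gene_a, gene_b, sign", call. = FALSE)
  }
  a <- normalize_symbol(as.character(edges$gene_a), synonyms = character(0))
  b <- normalize_symbol(as.character(edges$gene_b), synonyms = character(0))
  sgn <- edges$sign
  if (is.character(sgn)) {
    sgn <- ifelse(trimws(sgn) %in% c("+", "+1", "pos", "1"), 1,
                  ifelse(trimws(sgn) %in% c("-", "−", "-1", "neg"), -1, NA))
  }
  sgn <- as.integer(sgn)
  if (anyNA(sgn) || !all(sgn %in% c(-1L, 1L))) {
    stop("edge sign must be +1 or -1", call. = FALSE)
  }
  if (any(tolower(a) == tolower(b))) {
    stop("self-edges are not allowed in a seed network", call. = FALSE)
  }
  swap <- tolower(a) > tolower(b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  pair_key <- paste(tolower(a), tolower(b), sep = "\r")
  if (anyDuplicated(pair_key)) {
    dup <- duplicated(pair_key)
    same_sign <- vapply(which(dup), function(i) {
      sgn[i] == sgn[match(pair_key[i], pair_key)]
    }, logical(1))
    if (!all(same_sign)) {
      stop("duplicate edge with conflicting signs", call. = FALSE)
    }
    a <- a[!dup]; b <- b[!dup]; sgn <- sgn[!dup]
    prov_keep <- !dup
  } else {
    prov_keep <- rep(TRUE, length(a))
  }
  prov <- if ("provenance" %in% names(edges)) {
    as.character(edges$provenance)[prov_keep]
  } else rep(NA_character_, length(a))
  fly_nodes <- unique(c(a, b, if (!is.null(nodes)) normalize_symbol(nodes, character(0))))
  structure(
    list(fly_nodes = fly_nodes,
         fly_edges = data.frame(gene_a = a, gene_b = b, sign = sgn,
                                provenance = prov, stringsAsFactors = FALSE)),
    class = "seed_network_spec"
  )
}

#' @export
print.seed_network_spec <- function(x, ...) {
  cat(sprintf("<seed_network_spec> %d fly genes, %d signed edges (%d+, %d-)\n",
              length(x$fly_nodes), nrow(x$fly_edges),
              sum(x$fly_edges$sign > 0), sum(x$fly_edges$sign < 0)))
  invisible(x)
}

#' Read a signed seed network from three-column TSV
#'
#' Columns: gene_a, gene_b, sign (`+`/`-` or `+1`/`-1`); optional fourth
#' column is free-text provenance. A header line starting with "gene" is
#' skipped.
#'
#' @param path Path to TSV.
#' @return A [seed_network_spec()].
#' @export
read_seed_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^gene", tolower(lines[[1]]))) lines <- lines[-1]
  if (length(lines) == 0) stop(sprintf("'%s': no edges", path), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop(sprintf("'%s': each edge row needs gene_a, gene_b, sign", path), call. = FALSE)
  }
  seed_network_spec(data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1),
    gene_b = vapply(parts, `[[`, character(1), 2),
    sign = vapply(parts, `[[`, character(1), 3),
    provenance = vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_,
                        character(1)),
    stringsAsFactors = FALSE
  ))
}

#' Packaged fly-to-mouse homolog table
#'
#' The literature-curated mapping from the 18 fly retinal-determination
#' genes to their putative mouse homologs, as shipped in
#' `inst/extdata/fly_homologs.tsv`. One-to-many entries (e.g.
#' `eya -> Eya1/Eya2/Eya3`) and many-to-one entries (`toy` and `ey` both
#' to `Pax6`) are both present; `Sdccag33` resolves to `Tshz1` through the
#' default synonym table.
#'
#' @inheritParams homolog_map
#' @return A [homolog_map()].
#' @export
fly_homolog_map <- function(synonyms = default_synonyms()) {
  read_homolog_map(system.file("extdata", "fly_homologs.tsv", package = "seednet",
                               mustWork = TRUE), synonyms)
}

#' Packaged fly seed network (synthetic reconstruction)
#'
#' The original curated seed-network figure is not machine-readable; the
#' packaged edge list (`inst/extdata/fly_seed_network_synthetic.tsv`) is a
#' synthetic stand-in reconstructed from canonical retinal-determination
#' relationships reported across the fly literature (eyeless/sine
#' oculis/eyes absent/dachshund cross-activation, hedgehog and
#' decapentaplegic signaling inputs, Notch-mediated repression of atonal,
#' wingless antagonism). It covers all 18 fly genes with signed undirected
#' edges and is intended as a realistic default input, not as a faithful
#' copy of any published figure.
#'
#' @return A [seed_network_spec()].
#' @export
fly_seed_network <- function() {
  read_seed_network(system.file("extdata", "fly_seed_network_synthetic.tsv",
                                package = "seednet", mustWork = TRUE))
}
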