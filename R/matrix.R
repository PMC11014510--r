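#' Species-by-gene presence/absence matrix
#'
#' The central container of the pipeline: a binary grid with one row per
#' species and one column per gene, 1 = gene present, 0 = gene lost,
#' `NA` = unknown (written as `?` in text formats).
#'
#' @param states Matrix (coercible to integer) with entries in {0, 1, NA}.
#' @param species,genes Optional label vectors; default to dimnames.
#' @return A `presence_matrix`: list with elements `species`, `genes`,
#'   `states`.
#' @export
presence_matrix <- function(states, species = rownames(states),
                            genes = colnames(states)) {
  states <- as.matrix(states)
  if (is.null(species) || is.null(genes))
    stop("species and gene labels are required")
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L, NA_integer_)))
    stop("states must be 0, 1 or NA")
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (nrow(states) != length(species) || ncol(states) != length(genes))
    stop("dimension mismatch between states and labels")
  dimnames(states) <- list(species, genes)
  structure(list(species = as.character(species),
                 genes = as.character(genes),
                 states = states),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  nlost <- sum(x$states == 0L, na.rm = TRUE)
  cat(sprintf("presence_matrix: %d species x %d genes (%d lost states, %d unknown)\n",
              length(x$species), length(x$genes), nlost, sum(is.na(x$states))))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$states)

#' Parse a TOGA loss-summary stream
#'
#' TOGA `loss_summ_data.tsv` files carry one classification per line:
#' an entry class (`GENE`, `TRANSCRIPT` or `PROJECTION`), an identifier,
#' and a status code such as `I` (intact) or `L` (lost). The status
#' vocabulary is open-ended across TOGA releases, so any non-empty token is
#' accepted; only membership in the loss set matters downstream.
#'
#' @param x Character vector of lines, or a file path (single string naming
#'   an existing file).
#' @return Data frame with columns `entry_class`, `identifier`, `status`.
#' @export
parse_toga_summary <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  keep <- nzchar(trimws(lines))
  out <- data.frame(entry_class = character(0), identifier = character(0),
                    status = character(0), stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    bad <- idx[nfield < 3][1]
    stop("malformed TOGA line ", bad, ": expected >= 3 tab-separated fields")
  }
  data.frame(entry_class = vapply(parts, `[[`, "", 1),
             identifier = vapply(parts, `[[`, "", 2),
             status = vapply(parts, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Code TOGA gene records as binary presence states
#'
#' Only `GENE` rows are considered. A gene is coded 0 (lost) iff its status
#' is in `loss_statuses`; every other status is collapsed into a likely
#' present category and coded 1. The default loss set `{"L"}` is the
#' conservative coding; add `"UL"` (uncertain loss) or `"PI"` (partially
#' intact) to treat weaker evidence as loss. Duplicate gene rows with
#' conflicting statuses resolve by the any-loss-wins rule, with a warning.
#'
#' @param records Data frame from [parse_toga_summary()].
#' @param loss_statuses Character vector of status tokens coded as loss.
#' @return Named integer vector, gene -> 0/1.
#' @export
code_presence <- function(records, loss_statuses = "L") {
  g <- records[records$entry_class == "GENE", , drop = FALSE]
  if (nrow(g) == 0) return(stats::setNames(integer(0), character(0)))
  state <- ifelse(g$status %in% loss_statuses, 0L, 1L)
  agg <- tapply(state, g$identifier, min)  # any loss => 0
  n_states <- tapply(state, g$identifier, function(s) length(unique(s)))
  conflicted <- names(n_states)[n_states > 1]
  if (length(conflicted) > 0)
    warning("conflicting duplicate statuses resolved to loss for: ",
            paste(conflicted, collapse = ", "))
  out <- as.integer(agg)
  names(out) <- names(agg)
  out[unique(g$identifier)]  # preserve first-appearance order
}

#' Assemble per-species codings into a presence matrix
#'
#' @param per_species Named list (one element per species) of named 0/1
#'   vectors as returned by [code_presence()].
#' @param universe_policy How to build the gene universe: `"union"` of all
#'   per-species gene lists, `"intersection"`, or `"reference"` (an explicit
#'   list via `reference`).
#' @param fill_state State given to a gene missing from a species' file
#'   (union/reference policies). Defaults to 1, matching the collapse of all
#'   non-loss TOGA categories into likely-present.
#' @param reference Character vector of gene ids (policy `"reference"`).
#' @return A [presence_matrix()]; attribute `filled` counts filled cells per
#'   species.
#' @export
assemble_matrix <- function(per_species,
                            universe_policy = c("union", "intersection", "reference"),
                            fill_state = 1L, reference = NULL) {
  universe_policy <- match.arg(universe_policy)
  if (length(per_species) < 2) stop("need at least two species")
  if (is.null(names(per_species)) || anyDuplicated(names(per_species)))
    stop("per_species must be uniquely named by species")
  gene_lists <- lapply(per_species, names)
  genes <- switch(universe_policy,
    union = Reduce(union, gene_lists),
    intersection = Reduce(intersect, gene_lists),
    reference = {
      if (is.null(reference)) stop("reference policy needs a reference gene list")
      unique(reference)
    })
  if (length(genes) == 0) stop("empty gene universe under policy '", universe_policy, "'")
  states <- matrix(NA_integer_, length(per_species), length(genes),
                   dimnames = list(names(per_species), genes))
  filled <- stats::setNames(integer(length(per_species)), names(per_species))
  for (sp in names(per_species)) {
    v <- per_species[[sp]]
    hit <- intersect(genes, names(v))
    states[sp, hit] <- v[hit]
    miss <- setdiff(genes, names(v))
    states[sp, miss] <- as.integer(fill_state)
    filled[sp] <- length(miss)
  }
  m <- presence_matrix(states)
  attr(m, "filled") <- filled
  m
}

#' Remove blacklisted gene families from a matrix
#'
#' Gene families with problematic one-to-one orthology (keratins,
#' beta-defensins, uncharacterized ORFs, ...) are excluded before
#' phylogenetic or enrichment analysis. Patterns are exact gene symbols or
#' globs (`"KRT*"`).
#'
#' @param matrix A [presence_matrix()].
#' @param blacklist Character vector of patterns; empty vector is a no-op.
#' @return Filtered `presence_matrix`; attribute `removed` holds the dropped
#'   gene ids.
#' @export
filter_blacklist <- function(matrix, blacklist) {
  if (length(blacklist) == 0) {
    attr(matrix, "removed") <- character(0)
    return(matrix)
  }
  hit <- vapply(matrix$genes, function(g)
    any(vapply(blacklist, function(p) grepl(utils::glob2rx(p), g), FALSE)),
    FALSE)
  removed <- matrix$genes[hit]
  keep <- !hit
  if (!any(keep)) {
    warning("all genes removed by blacklist")
    out <- structure(list(species = matrix$species, genes = character(0),
                          states = matrix$states[, 0, drop = FALSE]),
                     class = "presence_matrix")
  } else {
    out <- presence_matrix(matrix$states[, keep, drop = FALSE])
  }
  attr(out, "removed") <- removed
  out
}

#' Default blacklist of problematic gene families
#'
#' Families whose orthology assignments are unreliable in genome-alignment
#' based annotation: uncharacterized ORFs, beta-defensins, FAM genes,
#' histones, keratins and keratin-associated proteins, NPIPA/NPIPB, PRAME,
#' solute carriers, SPATA, ubiquitin-specific peptidases, zinc fingers
#' (ZFP/ZSCAN) and UDP glucuronosyltransferases.
#'
#' @return Character vector of glob patterns.
#' @export
default_blacklist <- function() {
  c("C*orf*", "DEFB*", "FAM*", "HIST*", "KRT*", "KRTAP*", "NPIPA*", "NPIPB*",
    "PRAME*", "SLC*", "SPATA*", "USP*", "ZFP*", "ZSCAN*", "UGT*")
}

#' Read a blacklist file (one pattern per line, '#' comments)
#' @param file Path.
#' @return Character vector of patterns.
#' @export
read_blacklist <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a presence matrix to a text format
#'
#' Supported formats: `tsv` (species rows, gene columns, `?` for unknown),
#' `phylip` (classic discrete PHYLIP infile: header `<nspecies> <ngenes>`,
#' names padded/truncated to 10 characters), and `nexus` (DATA block with
#' `datatype=standard symbols="01"`). tsv and nexus round-trip through
#' [read_matrix()] exactly.
#'
#' @param matrix A [presence_matrix()].
#' @param file Output path.
#' @param format One of `"tsv"`, `"phylip"`, `"nexus"`.
#' @return `file`, invisibly.
#' @export
write_matrix <- function(matrix, file, format = c("tsv", "phylip", "nexus")) {
  format <- match.arg(format)
  chr <- matrix$states
  mode(chr) <- "character"
  chr[is.na(chr)] <- "?"
  rows <- apply(chr, 1, paste, collapse = "")
  lines <- switch(format,
    tsv = c(paste(c("species", matrix$genes), collapse = "\t"),
            vapply(seq_along(matrix$species), function(i)
              paste(c(matrix$species[i], chr[i, ]), collapse = "\t"), "")),
    phylip = {
      nm <- substr(matrix$species, 1, 10)
      if (anyDuplicated(nm))
        stop("species names collide after 10-character truncation: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
      c(paste(length(matrix$species), length(matrix$genes)),
        paste0(formatC(nm, width = -10), rows))
    },
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                      length(matrix$species), length(matrix$genes)),
              "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
              "  MATRIX",
              paste0("    ", matrix$species, "  ", rows),
              "  ;", "END;",
              paste0("[genes: ", paste(matrix$genes, collapse = " "), "]")))
  writeLines(lines, file)
  invisible(file)
}

#' Read a presence matrix written by [write_matrix()]
#'
#' @param file Path.
#' @param format `"tsv"` or `"nexus"`.
#' @return A [presence_matrix()]. For nexus, gene identifiers are recovered
#'   from the trailing comment block when present, else autogenerated.
#' @export
read_matrix <- function(file, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(file)
  if (format == "tsv") {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    genes <- header[-1]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    species <- vapply(body, `[[`, "", 1)
    states <- t(vapply(body, function(p) {
      v <- p[-1]
      as.integer(ifelse(v == "?", NA, v))
    }, integer(length(genes))))
    return(presence_matrix(states, species = species, genes = genes))
  }
  i0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (length(i0) != 1) stop("no MATRIX block found")
  rows <- list(); species <- character(0)
  for (ln in lines[(i0 + 1):length(lines)]) {
    ln <- trimws(ln)
    if (ln == ";") break
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    species <- c(species, parts[1])
    rows[[length(rows) + 1]] <- strsplit(parts[2], "")[[1]]
  }
  states <- t(vapply(rows, function(r) as.integer(ifelse(r == "?", NA, r)),
                     integer(length(rows[[1]]))))
  gl <- grep("^\\[genes:", lines, value = TRUE)
  genes <- if (length(gl) == 1) {
    strsplit(sub("^\\[genes: *(.*)\\]$", "\\1", gl), " +")[[1]]
  } else paste0("g", seq_len(ncol(states)))
  presence_matrix(states, species = species, genes = genes)
}
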