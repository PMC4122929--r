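# Readers and writers for the plain-text formats the pipeline touches:
# FASTA sequences, 12-column tabular similarity hits, and two-column TSV
# maps (isogroup, linkage, GO, coding-potential scores). Sequences travel
# as tibbles with columns id / seq / desc so everything chains with dplyr.

.valid_dna <- function(seq) grepl("^[ACGTN]+$", seq)

#' Read a DNA FASTA file into a sequence tibble
#'
#' Residues are uppercased; ids must be unique, non-empty tokens; sequences
#' must be non-empty and restricted to the A/C/G/T/N alphabet (the codon
#' logic downstream requires a fixed alphabet).
#'
#' @param path FASTA file.
#' @return A tibble with columns `id`, `seq`, `desc`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(id = character(), seq = character(), desc = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) abort("malformed FASTA: first line is not a header")
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  # headers with no sequence lines are absent from `seqs`
  full <- character(length(ids))
  full[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(ids))) abort("malformed FASTA: empty sequence id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  if (any(!nzchar(full))) {
    abort(paste0("empty sequence for id: ", ids[!nzchar(full)][1]))
  }
  ok <- .valid_dna(full)
  if (any(!ok)) {
    abort(paste0("non-ACGTN residues in sequence: ", ids[!ok][1]))
  }
  tibble(id = ids, seq = unname(full), desc = desc)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `id`, `seq` (and optionally `desc`).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  hdr <- paste0(">", seqs$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  chunks <- map2(seqs$seq, hdr, function(s, h) {
    starts <- seq(1, nchar(s), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

.read_two_col <- function(path, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(tibble(key = character(), value = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(paste0("malformed ", what, " row at line ", bad[1],
                 ": expected 2 tab-separated columns"))
  }
  tibble(key = vapply(parts, `[[`, "", 1),
         value = vapply(parts, `[[`, "", 2))
}

#' Read an isotig-to-isogroup map
#'
#' Two-column TSV (isotig id, isogroup id). An isotig listed under two
#' different isogroups is rejected by name. See [derive_isogroup_map()] for
#' grouping encoded in sequence identifiers instead of a file.
#'
#' @param path TSV file.
#' @return Tibble with columns `isotig_id`, `isogroup_id`.
#' @export
read_isogroup_map <- function(path) {
  tbl <- .read_two_col(path, "isogroup map")
  out <- tibble(isotig_id = tbl$key, isogroup_id = tbl$value) |> distinct()
  dup <- out$isotig_id[duplicated(out$isotig_id)]
  if (length(dup)) {
    abort(paste0("isotig mapped to more than one isogroup: ", dup[1]))
  }
  out
}

#' Derive an isogroup map from an id pattern
#'
#' For assemblies that encode the gene grouping in the identifier itself,
#' `pattern` is a regular expression with one capture group extracting the
#' isogroup label from each isotig id. Ids that do not match become
#' singleton isogroups (mapped to themselves).
#'
#' @param ids character vector of isotig ids.
#' @param pattern regex with one capture group.
#' @return Tibble with columns `isotig_id`, `isogroup_id`.
#' @export
derive_isogroup_map <- function(ids, pattern) {
  m <- regmatches(ids, regexec(pattern, ids))
  grp <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  tibble(isotig_id = ids, isogroup_id = ifelse(is.na(grp), ids, grp))
}

.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read similarity hits in 12-column tabular format
#'
#' The standard tab-separated hit table (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Coordinates
#' stay 1-based inclusive; minus-strand subject hits carry `sstart > send`.
#'
#' @param path hit table file.
#' @return Tibble with the 12 standard columns.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("hit file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(qseqid = character(), sseqid = character(),
                  pident = double(), length = integer(),
                  mismatch = integer(), gapopen = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = double(), bitscore = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad)) {
    abort(paste0("malformed hit row at line ", bad[1],
                 ": expected 12 tab-separated columns, got ",
                 lengths(parts)[bad[1]]))
  }
  m <- do.call(rbind, parts)
  tibble(qseqid = m[, 1], sseqid = m[, 2],
         pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
         mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
         qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
         sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
         evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
}

#' Write similarity hits in 12-column tabular format
#'
#' @param hits tibble as returned by [read_tabular_hits()] or the internal
#'   search; extra columns are dropped.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  stopifnot(all(.hit_cols %in% names(hits)))
  rows <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                  hits$qseqid, hits$sseqid, hits$pident,
                  as.integer(hits$length), as.integer(hits$mismatch),
                  as.integer(hits$gapopen), as.integer(hits$qstart),
                  as.integer(hits$qend), as.integer(hits$sstart),
                  as.integer(hits$send),
                  formatC(hits$evalue, format = "e", digits = 2),
                  hits$bitscore)
  writeLines(rows, path)
  invisible(path)
}

#' Read a genome-contig to chromosome linkage map
#'
#' @param path two-column TSV (contig id, chromosome id).
#' @return Tibble with columns `contig_id`, `chromosome`.
#' @export
read_linkage_map <- function(path) {
  tbl <- .read_two_col(path, "linkage map")
  out <- tibble(contig_id = tbl$key, chromosome = tbl$value) |> distinct()
  dup <- out$contig_id[duplicated(out$contig_id)]
  if (length(dup)) {
    abort(paste0("contig mapped to more than one chromosome: ", dup[1]))
  }
  out
}

#' Read a GO annotation map
#'
#' Two-column TSV (sequence id, GO term); multiple rows per id accumulate
#' into a term set, duplicates collapse (set semantics).
#'
#' @param path TSV file.
#' @return Tibble with columns `id`, `go_term`, one row per distinct pair.
#' @export
read_go_map <- function(path) {
  tbl <- .read_two_col(path, "GO map")
  bad <- !grepl("^GO:\\d{7}$", tbl$value)
  if (any(bad)) {
    abort(paste0("invalid GO term identifier: '", tbl$value[bad][1], "'"))
  }
  tibble(id = tbl$key, go_term = tbl$value) |> distinct()
}

#' Read a per-sequence coding-potential score table
#'
#' @param path two-column TSV (sequence id, score in \[0, 1\]).
#' @return Tibble with columns `id`, `score`.
#' @export
read_score_table <- function(path) {
  tbl <- .read_two_col(path, "score table")
  score <- suppressWarnings(as.numeric(tbl$value))
  bad <- is.na(score) | score < 0 | score > 1
  if (any(bad)) {
    abort(paste0("coding-potential score outside [0,1] for id: ",
                 tbl$key[bad][1]))
  }
  tibble(id = tbl$key, score = score)
}

#' Read a best-annotation-hit table
#'
#' Two-column TSV (sequence id, best-hit accession). Ids absent from the
#' table simply have no hit; an empty or `NA` accession also means no hit.
#'
#' @param path TSV file.
#' @return Tibble with columns `id`, `accession`.
#' @export
read_annotation_hits <- function(path) {
  tbl <- .read_two_col(path, "annotation hit table")
  tibble(id = tbl$key,
         accession = ifelse(tbl$value %in% c("", "NA"), NA_character_,
                            tbl$value)) |>
    distinct()
}
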