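# Readers and writers for the standard formats the pipeline touches:
# FASTA (Biostrings), BLAST tabular outfmt-6, Newick (ape), taxonomy TSV.

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order",
                    "family", "genus", "species")

# Treat a character scalar as inline text when it contains a newline or
# starts like the format itself; otherwise as a file path.
as_input_file <- function(x, inline = FALSE) {
  if (inline || grepl("\n", x)) {
    f <- tempfile()
    writeLines(sub("\n$", "", x), f)
    return(f)
  }
  x
}

#' Read sequences from FASTA
#'
#' Sequence lines are concatenated, whitespace stripped and letters folded to
#' upper case; record order is preserved.
#'
#' @param x path to a FASTA file, or the FASTA text itself (anything
#'   containing a newline is treated as inline text).
#' @return named character vector of sequences (names are the full header
#'   lines up to the first whitespace).
#' @export
read_fasta <- function(x) {
  if (length(x) == 1L && grepl("\n", x)) {
    f <- tempfile(fileext = ".fa")
    writeLines(x, f)
  } else if (length(x) == 1L && (startsWith(x, ">") || !file.exists(x))) {
    if (!startsWith(x, ">") && !file.exists(x)) stop("file not found: ", x)
    f <- tempfile(fileext = ".fa")
    writeLines(x, f)
  } else {
    f <- x
  }
  lines <- readLines(f, warn = FALSE)
  body <- lines[nzchar(trimws(lines))]
  if (length(body) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(body[1L], ">"))
    stop("FASTA format error: sequence line before any header")
  set <- Biostrings::readBStringSet(f)
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a BLAST tabular (outfmt 6) hit table
#'
#' Twelve tab-separated columns per row; `#` comment lines are skipped.
#' Minus-strand subject hits (sstart > send) are kept as printed; use
#' [hit_subject_range()] for normalised coordinates.
#'
#' @param x path or inline text.
#' @return data.frame with columns qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
parse_hit_table <- function(x) {
  f <- as_input_file(x, inline = length(x) == 1L && grepl("\t", x) && !file.exists(x))
  lines <- readLines(f, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(empty_hit_table())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- keep[which(nf != 12L)[1L]]
    stop("hit table format error: expected 12 columns at line ", bad,
         " (got ", nf[which(nf != 12L)[1L]], ")")
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  bad <- which(out$qstart > out$qend)
  if (length(bad))
    stop("hit table error: qstart > qend at data row ", bad[1L])
  out
}

empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST outfmt-6 layout
#' @param hits data.frame as returned by [parse_hit_table()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(identical(names(hits), HIT_COLS))
  lines <- apply(hits, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Normalised subject coordinates and strand for hits
#'
#' @param hits hit table data.frame.
#' @return data.frame with columns smin, smax, strand ("+" when
#'   sstart <= send, "-" otherwise).
#' @export
hit_subject_range <- function(hits) {
  data.frame(
    smin = pmin(hits$sstart, hits$send),
    smax = pmax(hits$sstart, hits$send),
    strand = ifelse(hits$sstart <= hits$send, "+", "-"),
    stringsAsFactors = FALSE
  )
}

#' Parse a Newick tree
#'
#' Numeric internal-node labels are interpreted downstream as bootstrap
#' support values (see [node_supports()]).
#'
#' @param x a Newick string (must contain "(") or a file path.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(x) {
  tr <- tryCatch(
    if (length(x) == 1L && grepl("[(;]", x)) ape::read.tree(text = x)
    else ape::read.tree(x),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error (unbalanced parentheses or malformed input)")
  tr
}

#' Serialise a tree to Newick
#' @param tree an `ape::phylo` tree.
#' @return a single Newick string terminated by ";".
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Numeric support values for internal nodes
#'
#' @param tree an `ape::phylo` tree whose `node.label` holds supports.
#' @return numeric vector, one entry per internal node (NA where the label is
#'   absent or non-numeric).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Read a host taxonomy table
#'
#' Tab-separated with header
#' `lineage_id kingdom phylum class order family genus species`; empty cells
#' are allowed below the deepest known rank.
#'
#' @param x path or inline text.
#' @return data.frame of character columns; `lineage_id` is unique.
#' @export
read_taxonomy <- function(x) {
  f <- as_input_file(x, inline = length(x) == 1L && grepl("\t", x) && !file.exists(x))
  tab <- utils::read.delim(f, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  need <- c("lineage_id", TAXONOMY_RANKS)
  if (!identical(names(tab), need))
    stop("taxonomy table must have columns: ", paste(need, collapse = " "))
  if (anyDuplicated(tab$lineage_id))
    stop("taxonomy table: duplicated lineage_id")
  tab
}

#' Write a host taxonomy table
#' @param tax data.frame as returned by [read_taxonomy()].
#' @param path output file.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
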