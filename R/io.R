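#' Read and write pipeline file formats
#'
#' Gene models travel as GFF3 (1-based inclusive on disk, converted to the
#' package-internal 0-based half-open convention on read), TE annotations as
#' 6-column BED (native 0-based) or RepeatMasker `.out` (1-based), and
#' everything else as TSV.
#'
#' @name texpress-io
NULL

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene plus its `exon` and `CDS` children with
#' `ID`/`Parent` attributes. Output is byte-deterministic for a fixed input.
#'
#' @param genes gene-model table: columns `gene_id`, `chrom`, `strand`,
#'   `feature` (`"CDS"`/`"exon"`), `start`, `end` (0-based half-open)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "strand", "feature", "start", "end") %in% names(genes)))
  dt <- data.table::as.data.table(genes)
  data.table::setorder(dt, chrom, start, gene_id, feature)
  lines <- c("##gff-version 3")
  for (gid in unique(dt$gene_id)) {
    g <- dt[dt$gene_id == gid, ]
    lines <- c(lines, paste(
      g$chrom[1L], "texpress", "gene",
      min(g$start) + 1L, max(g$end), ".", g$strand[1L], ".",
      paste0("ID=", gid), sep = "\t"
    ))
    for (i in seq_len(nrow(g))) {
      lines <- c(lines, paste(
        g$chrom[i], "texpress", g$feature[i],
        g$start[i] + 1L, g$end[i], ".", g$strand[i],
        if (g$feature[i] == "CDS") "0" else ".",
        paste0("ID=", gid, ":", tolower(g$feature[i]), ":", i, ";Parent=", gid),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `CDS` and `exon` features; the gene id is taken from the `Parent`
#' attribute (or `ID` when `Parent` is absent). Coordinates are converted to
#' 0-based half-open.
#'
#' @param path GFF3 file
#' @return gene-model table (see [write_gff3()])
#' @export
read_gff3 <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = FALSE, skip = "#",
                           col.names = c("chrom", "source", "feature", "start", "end",
                                         "score", "strand", "frame", "attributes"),
                           colClasses = list(character = c(1, 2, 3, 6, 7, 8, 9)))
  raw <- raw[raw$feature %in% c("CDS", "exon"), ]
  get_attr <- function(attrs, key) {
    hit <- grepl(paste0("(^|;)", key, "="), attrs)
    out <- rep(NA_character_, length(attrs))
    out[hit] <- sub(paste0(".*(^|;)", key, "=([^;]+).*"), "\\2", attrs[hit])
    out
  }
  parent <- get_attr(raw$attributes, "Parent")
  id <- get_attr(raw$attributes, "ID")
  gene_id <- ifelse(is.na(parent), id, parent)
  data.frame(
    gene_id = gene_id, chrom = raw$chrom, strand = raw$strand,
    feature = raw$feature, start = raw$start - 1L, end = raw$end,
    stringsAsFactors = FALSE
  )
}

#' Write TE annotations as BED6
#'
#' The name field encodes `te_id#te_type` (RepeatMasker library style) so the
#' TE class survives the round trip. Coordinates are BED-native 0-based.
#'
#' @param tes TE table: `te_id`, `chrom`, `start`, `end`, `te_type`,
#'   optional `strand`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_te_bed <- function(tes, path) {
  strand <- if ("strand" %in% names(tes)) tes$strand else rep("+", nrow(tes))
  dt <- data.table::data.table(
    chrom = tes$chrom, start = tes$start, end = tes$end,
    name = paste0(tes$te_id, "#", tes$te_type), score = 0L, strand = strand
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read TE annotations from BED6
#' @param path BED file written by [write_te_bed()] or with `name#class` names
#' @return TE table
#' @export
read_te_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "score", "strand"))
  parts <- data.table::tstrsplit(dt$name, "#", fixed = TRUE)
  data.frame(
    te_id = parts[[1L]], chrom = dt$chrom, start = dt$start, end = dt$end,
    te_type = if (length(parts) > 1L) parts[[2L]] else NA_character_,
    strand = dt$strand, stringsAsFactors = FALSE
  )
}

#' Write TE annotations in the RepeatMasker `.out` dialect
#'
#' 15 whitespace-separated columns with the standard two header lines and a
#' blank line; positions are 1-based inclusive. Alignment-score columns are
#' filled with placeholders since the simulator has no alignments.
#'
#' @inheritParams write_te_bed
#' @return `path`, invisibly
#' @export
write_rm_out <- function(tes, path) {
  strand <- if ("strand" %in% names(tes)) tes$strand else rep("+", nrow(tes))
  class_of <- c(DNA = "DNA/hAT", RC = "RC/Helitron", LTR = "LTR/Gypsy",
                LINE = "LINE/CR1", SINE = "SINE/tRNA")
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching  repeat          position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)     repeat    class/family    begin  end    (left)  ID",
    ""
  )
  len <- tes$end - tes$start
  body <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (%d) %d",
    1000L, 10.0, 0.0, 0.0, tes$chrom, tes$start + 1L, tes$end, 0L,
    ifelse(strand == "-", "C", "+"), tes$te_id,
    unname(class_of[tes$te_type]) %||% tes$te_type,
    1L, len, 0L, seq_len(nrow(tes))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read RepeatMasker `.out` files
#'
#' Handles the 15-column whitespace dialect with header lines; the TE class
#' is the `class/family` prefix before `/`. Coordinates become 0-based
#' half-open.
#'
#' @param path `.out` file
#' @return TE table (see [write_te_bed()])
#' @export
read_rm_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*(SW|score)\\b", lines)]
  if (length(lines) == 0L) {
    return(data.frame(te_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      te_type = character(0), strand = character(0)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, length, 0L) < 15L
  if (any(bad)) stop("malformed RepeatMasker .out row(s): ", which(bad)[1L])
  f <- function(i) vapply(fields, `[[`, "", i)
  data.frame(
    te_id = f(10L), chrom = f(5L),
    start = as.numeric(f(6L)) - 1L, end = as.numeric(f(7L)),
    te_type = sub("/.*$", "", f(11L)),
    strand = ifelse(f(9L) == "C", "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Write/read a counts matrix as TSV (gene_id + one column per sample)
#' @param counts numeric matrix with rownames
#' @param path file path
#' @return `path` / matrix
#' @export
write_counts_tsv <- function(counts, path) {
  dt <- data.table::data.table(gene_id = rownames(counts))
  for (s in colnames(counts)) dt[[s]] <- counts[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}

#' Write/read generic TSV tables (sample metadata, similarity scores,
#' alignment blocks, insertion records, ground truth)
#' @param x data.frame
#' @param path file path
#' @return `path` / data.frame
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
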