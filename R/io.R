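#' Read a FASTA file into an assembly
#'
#' Uses Biostrings for parsing; case is preserved exactly (the provenance
#' channel). Records containing characters outside `A,C,G,T,N` (either case)
#' are rejected with an error naming the offending record.
#'
#' @param path FASTA file.
#' @param version version tag for the returned assembly.
#' @return an [assembly].
#' @export
read_fasta <- function(path, version = "v0") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(assembly(stats::setNames(character(0), character(0)), version = version))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  # strip description after first whitespace, like most assembly tools
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly(seqs, version = version, meta = list(source = path))
}

#' Write an assembly to FASTA
#'
#' @param x an [assembly].
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "assembly"))
  ss <- Biostrings::BStringSet(x$seq)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

paf_cols <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")

#' Read pairwise alignments from PAF
#'
#' Parses the 12 mandatory PAF columns into an alignment-record data frame
#' with 0-based half-open coordinates (PAF's native convention, kept
#' internally). Optional SAM-style tags are ignored.
#'
#' @param path PAF file.
#' @return data.frame with columns qname, qlen, qstart, qend, strand, tname,
#'   tlen, tstart, tend, nmatch, alen, mapq.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) stop("PAF line with fewer than 12 columns: line ",
                          which(nf < 12L)[1])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- data.frame(qname = m[, 1], qlen = as.integer(m[, 2]),
                   qstart = as.integer(m[, 3]), qend = as.integer(m[, 4]),
                   strand = m[, 5], tname = m[, 6], tlen = as.integer(m[, 7]),
                   tstart = as.integer(m[, 8]), tend = as.integer(m[, 9]),
                   nmatch = as.integer(m[, 10]), alen = as.integer(m[, 11]),
                   mapq = as.integer(m[, 12]))
  validate_paf(df)
  df
}

empty_paf <- function() {
  data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), tname = character(0),
             tlen = integer(0), tstart = integer(0), tend = integer(0),
             nmatch = integer(0), alen = integer(0), mapq = integer(0))
}

validate_paf <- function(df) {
  bad <- df$qstart >= df$qend | df$tstart >= df$tend
  if (any(bad)) stop("coordinate inversion in PAF records: ",
                     paste(which(bad), collapse = ", "))
  bad_s <- !df$strand %in% c("+", "-")
  if (any(bad_s)) stop("invalid strand in PAF records: ",
                       paste(which(bad_s), collapse = ", "))
  invisible(df)
}

#' Write alignment records as PAF
#' @param df alignment-record data.frame (see [read_paf]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(df, path) {
  lines <- apply(df[, paf_cols, drop = FALSE], 1L, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Alignment identity of PAF-style records
#' @param df alignment-record data.frame.
#' @return numeric vector, matches / block length, in `[0, 1]`.
#' @export
aln_identity <- function(df) ifelse(df$alen > 0, df$nmatch / df$alen, 0)

#' Read a BED3+ file
#'
#' @param path BED file.
#' @return data.frame chrom, start, end (0-based half-open) plus any extra
#'   columns as `V4`, `V5`, ...
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop("coordinate inversion in BED: ",
                                    paste(which(df$start >= df$end), collapse = ", "))
  df
}

#' Write intervals as BED3
#' @param df data.frame with chrom, start, end (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF into a genotyped-variant table
#'
#' Minimal typed reader for the fields this package uses: CHROM, POS
#' (1-based), REF, ALT, the GT field of the first sample (if any), and the
#' AF/AN INFO keys when present. Multiallelic ALT strings are kept verbatim
#' (comma-separated).
#'
#' @param path VCF file (uncompressed).
#' @return data.frame chrom, pos, id, ref, alt, gt, af, an.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0), gt = character(0),
                      af = numeric(0), an = integer(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) stop("VCF data line with fewer than 8 columns: line ",
                         which(nf < 8L)[1])
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  info <- get(8L)
  info_key <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  gt <- rep(NA_character_, length(fields))
  has_sample <- nf >= 10L
  if (any(has_sample)) {
    fmt <- get(9L); smp <- get(10L)
    idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(k) match("GT", k), integer(1))
    gtv <- mapply(function(s, i) {
      if (is.na(i)) return(NA_character_)
      strsplit(s, ":", fixed = TRUE)[[1]][i]
    }, smp, idx, USE.NAMES = FALSE)
    gt[has_sample] <- gtv[has_sample]
  }
  data.frame(chrom = get(1L), pos = as.integer(get(2L)), id = get(3L),
             ref = get(4L), alt = get(5L), gt = gt,
             af = suppressWarnings(as.numeric(info_key("AF"))),
             an = suppressWarnings(as.integer(info_key("AN"))))
}

#' Write a genotyped-variant table as VCF 4.2
#'
#' @param df data.frame with chrom, pos, ref, alt and optionally id, gt, af,
#'   an columns.
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(df, path, sample = "SAMPLE", contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  has_gt <- "gt" %in% names(df) && any(!is.na(df$gt))
  cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                  if (has_gt) c("FORMAT", sample)), collapse = "\t")
  info <- rep(".", nrow(df))
  if ("af" %in% names(df)) {
    info <- ifelse(is.na(df$af), info, sprintf("AF=%.6g", df$af))
  }
  if ("an" %in% names(df)) {
    info <- ifelse(is.na(df$an), info,
                   ifelse(info == ".", sprintf("AN=%d", df$an),
                          paste0(info, ";AN=", df$an)))
  }
  id <- if ("id" %in% names(df)) ifelse(is.na(df$id), ".", df$id) else rep(".", nrow(df))
  body <- paste(df$chrom, df$pos, id, df$ref, df$alt, ".", ".", info, sep = "\t")
  if (has_gt) body <- paste(body, "GT", ifelse(is.na(df$gt), ".", df$gt), sep = "\t")
  writeLines(c(hdr, cols, body), path)
  invisible(path)
}

#' Read a coverage track (BED-graph-like TSV)
#'
#' @param path TSV with columns seq, start, end, depth (0-based half-open).
#' @return data.frame seq, start, end, depth.
#' @export
read_coverage <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq", "start", "end", "depth"),
                          stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$depth <- as.numeric(df$depth)
  df
}

#' Write a coverage track
#' @param df data.frame seq, start, end, depth.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(df, path) {
  utils::write.table(df[, c("seq", "start", "end", "depth")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tiling plan as AGP 2.1
#'
#' Component (`W`) rows carry contig name, interval (converted to 1-based
#' inclusive) and orientation; gap (`N`) rows carry the estimated gap size
#' with gap type `scaffold`, linkage `yes`, evidence `align_genus`.
#'
#' @param plan tiling-plan data.frame as produced by [build_chromosomes]:
#'   columns object, obj_start, obj_end (0-based half-open), type (`"W"` or
#'   `"N"`), comp, comp_start, comp_end, orient, gap_len.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(plan, path) {
  lines <- c("##agp-version\t2.1")
  for (obj in unique(plan$object)) {
    p <- plan[plan$object == obj, , drop = FALSE]
    p <- p[order(p$obj_start), , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      r <- p[i, ]
      if (r$type == "W") {
        lines <- c(lines, paste(obj, r$obj_start + 1L, r$obj_end, i, "W",
                                r$comp, r$comp_start + 1L, r$comp_end, r$orient,
                                sep = "\t"))
      } else {
        lines <- c(lines, paste(obj, r$obj_start + 1L, r$obj_end, i, "N",
                                r$gap_len, "scaffold", "yes", "align_genus",
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP 2.1 file back into a tiling plan
#' @param path AGP file.
#' @return tiling-plan data.frame (see [write_agp]).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(f, function(x) {
    if (x[5] %in% c("N", "U")) {
      data.frame(object = x[1], obj_start = as.integer(x[2]) - 1L,
                 obj_end = as.integer(x[3]), type = "N", comp = NA_character_,
                 comp_start = NA_integer_, comp_end = NA_integer_,
                 orient = NA_character_, gap_len = as.integer(x[6]))
    } else {
      data.frame(object = x[1], obj_start = as.integer(x[2]) - 1L,
                 obj_end = as.integer(x[3]), type = "W", comp = x[6],
                 comp_start = as.integer(x[7]) - 1L, comp_end = as.integer(x[8]),
                 orient = x[9], gap_len = NA_integer_)
    }
  })
  do.call(rbind, rows)
}

#' Read a GFF3 annotation into a feature table
#'
#' Parsed via rtracklayer; the returned data frame uses 1-based inclusive
#' coordinates (GFF convention) and flattens the ID/Parent attributes.
#'
#' @param path GFF3 file.
#' @return data.frame seqid, source, type, start, end, strand, phase, ID,
#'   Parent.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             source = if ("source" %in% names(mc)) as.character(mc$source) else "refcurate",
             type = as.character(mc$type),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             phase = if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_,
             ID = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
             Parent = parent)
}

#' Write a feature table as GFF3
#' @param df feature data.frame (see [read_gff3]), 1-based inclusive.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = ifelse(is.na(df$strand) | df$strand == ".", "*", df$strand))
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  if ("phase" %in% names(df)) S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a population allele-frequency site table
#'
#' @param path TSV with header columns chrom, pos (1-based), ref, alt, af, an.
#' @return data.frame with those columns.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "af", "an")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("site table missing columns: ",
                            paste(missing, collapse = ", "))
  # guard against type sniffing (e.g. an all-T allele column read as logical)
  for (col in c("chrom", "ref", "alt")) df[[col]] <- as.character(df[[col]])
  df$alt[df$alt == "TRUE"] <- "T"
  df$ref[df$ref == "TRUE"] <- "T"
  df
}

#' Write a population allele-frequency site table
#' @param df site data.frame (chrom, pos, ref, alt, af, an).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
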