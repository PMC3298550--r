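GENO_DIALECTS <- list(
  standard = c(AA = "AA", AB = "AB", BB = "BB", missing = "--"),
  joinmap  = c(AA = "a",  AB = "h",  BB = "b",  missing = "-")
)

#' Read and write genotype matrices
#'
#' Delimited text, marker-major: first column the marker id, remaining
#' columns one individual each. Two code dialects are supported:
#' `"standard"` (`AA`/`AB`/`BB`/`--`) and the JoinMap-style `"joinmap"`
#' (`a`/`h`/`b`/`-`). `AA` is the P1 homozygote.
#'
#' @param path File path.
#' @param dialect Genotype code dialect.
#' @param sep Field separator.
#' @return `read_genotypes()` returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("standard", "joinmap"),
                           sep = "\t") {
  dialect <- match.arg(dialect)
  codes <- GENO_DIALECTS[[dialect]]
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("genotype file needs a marker column plus individuals")
  markers <- df[[1L]]
  if (anyDuplicated(markers)) {
    stop("duplicated marker id(s): ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  calls <- as.matrix(df[, -1L, drop = FALSE])
  known <- base::matrix(calls %in% codes, nrow = nrow(calls))
  if (any(!known)) {
    bad <- which(!known, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown genotype code %s at marker %s (line %d) under dialect '%s'",
                 dQuote(calls[bad[1L], bad[2L]]), markers[bad[1L]],
                 bad[1L] + 1L, dialect))
  }
  decoded <- c(GENO_CODES, NA_character_)[match(calls, codes)]
  genotype_matrix(base::matrix(decoded, nrow = nrow(calls)),
                  markers = markers, individuals = colnames(calls))
}

#' @rdname read_genotypes
#' @param matrix A [genotype_matrix()].
#' @export
write_genotypes <- function(matrix, path, dialect = c("standard", "joinmap"),
                            sep = "\t") {
  dialect <- match.arg(dialect)
  codes <- GENO_DIALECTS[[dialect]]
  enc <- codes[c(match(matrix, GENO_CODES))]
  enc[is.na(enc)] <- codes[["missing"]]
  out <- data.frame(marker = rownames(matrix),
                    base::matrix(enc, nrow = nrow(matrix)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("marker", colnames(matrix))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genetic map tables
#'
#' Delimited text with columns `group`, `marker`, `pos_cM`, mirroring the
#' common genetic-map table layout.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_map()` returns a `genetic_map`.
#' @export
read_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("group", "marker", "pos_cM")
  if (!all(need %in% names(df))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$marker)) stop("duplicated marker id in map file")
  df <- df[order(df$group, df$pos_cM), need]
  rownames(df) <- NULL
  df$marker <- as.character(df$marker)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @rdname read_map
#' @param map A `genetic_map`.
#' @export
write_map <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(as.data.frame(map)[, c("group", "marker", "pos_cM")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homolog table
#'
#' Delimited text with columns `marker`, `map_chrom`, `ref_chrom` and
#' optionally `ref_genome` (otherwise supplied via `ref_genome=`) and
#' `evalue` (ignored; E-value filtering is assumed done upstream).
#'
#' @param path File path.
#' @param ref_genome Reference genome label (used when the file lacks a
#'   `ref_genome` column; files carrying one may hold several genomes, in
#'   which case a named list of tables is returned).
#' @param include_unanchored Passed to [homolog_table()].
#' @param sep Field separator.
#' @return A [homolog_table()], or a named list of them.
#' @export
read_homologs <- function(path, ref_genome = "reference",
                          include_unanchored = FALSE, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("marker", "map_chrom", "ref_chrom")
  if (!all(need %in% names(df))) {
    stop("homolog file must have columns: ", paste(need, collapse = ", "))
  }
  build <- function(d, label) {
    homolog_table(d$marker, d$map_chrom, d$ref_chrom, ref_genome = label,
                  include_unanchored = include_unanchored)
  }
  if ("ref_genome" %in% names(df)) {
    parts <- split(df, df$ref_genome)
    out <- lapply(names(parts), function(g) build(parts[[g]], g))
    names(out) <- names(parts)
    if (length(out) == 1L) out[[1L]] else out
  } else {
    build(df, ref_genome)
  }
}

#' Read transcripts with CDS coordinates
#'
#' Reads a FASTA file of transcript sequences plus a delimited CDS table
#' with columns `transcript`, `cds_start`, `cds_end` (1-based inclusive).
#'
#' @param fasta_path FASTA file of transcript sequences.
#' @param cds_path Delimited CDS coordinate table.
#' @param sep Field separator of the CDS table.
#' @return Named list of [transcript_record()] objects.
#' @export
read_transcripts <- function(fasta_path, cds_path, sep = "\t") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cds <- utils::read.table(cds_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("transcript", "cds_start", "cds_end")
  if (!all(need %in% names(cds))) {
    stop("CDS table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(cds$transcript, ids)
  if (length(missing)) {
    stop("CDS table names transcripts absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(cds)), function(i) {
    transcript_record(cds$transcript[i],
                      as.character(seqs[[match(cds$transcript[i], ids)]]),
                      cds$cds_start[i], cds$cds_end[i])
  })
  names(out) <- cds$transcript
  out
}

#' Read SNP site table
#'
#' Delimited text with columns `marker`, `anchor`, `offset`, `allele_p1`,
#' `allele_p2`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return List of [snp_site()] objects.
#' @export
read_snp_sites <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("marker", "anchor", "offset", "allele_p1", "allele_p2")
  if (!all(need %in% names(df))) {
    stop("SNP site table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    snp_site(df$marker[i], df$anchor[i], df$offset[i],
             df$allele_p1[i], df$allele_p2[i])
  })
}
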