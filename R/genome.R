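#' Genome model for cross simulation
#'
#' A genome model is the simulation truth for a mapping cross: a set of
#' chromosomes, each carrying ordered markers at known genetic positions
#' (cM from the chromosome start). It is stored as a data frame with columns
#' `chrom`, `marker` and `pos_cM`.
#'
#' @param chrom Chromosome identifier per marker.
#' @param marker Marker identifier per marker; must be globally unique.
#' @param pos_cM Genetic position in cM from the chromosome start;
#'   non-decreasing within a chromosome.
#' @return An object of class `genome_model` (a data frame).
#' @examples
#' genome_model(chrom = c(1, 1, 2), marker = c("a", "b", "c"),
#'              pos_cM = c(0, 10, 0))
#' @export
genome_model <- function(chrom, marker, pos_cM) {
  if (length(chrom) != length(marker) || length(marker) != length(pos_cM)) {
    stop("`chrom`, `marker` and `pos_cM` must have equal length")
  }
  if (length(marker) == 0L) stop("a genome model needs at least one marker")
  marker <- as.character(marker)
  if (anyDuplicated(marker)) stop("marker ids must be globally unique")
  if (any(is.na(pos_cM)) || any(pos_cM < 0)) stop("positions must be non-negative")
  g <- data.frame(chrom = as.character(chrom), marker = marker,
                  pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  # keep input order within chromosomes but require it to be sorted
  for (ch in unique(g$chrom)) {
    p <- g$pos_cM[g$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Default study-scale genome
#'
#' Builds the default genome used for study-scale simulations: `n_chrom`
#' chromosomes whose genetic lengths are evenly spread between `min_length`
#' and `max_length` cM, carrying `n_markers` markers allocated proportionally
#' to chromosome length (largest-remainder rounding, at least two per
#' chromosome) and spaced uniformly from 0 to the chromosome length.
#'
#' Defaults emulate a 12-chromosome copepod map with 190 markers and group
#' lengths spanning 19-32 cM.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_markers Total marker count.
#' @param min_length,max_length Range of chromosome genetic lengths (cM).
#' @return A [genome_model()].
#' @export
default_genome <- function(n_chrom = 12, n_markers = 190,
                           min_length = 19, max_length = 32) {
  if (n_chrom < 1 || n_markers < 2 * n_chrom) {
    stop("need at least two markers per chromosome")
  }
  lens <- seq(min_length, max_length, length.out = n_chrom)
  # largest-remainder allocation proportional to length, minimum 2
  quota <- n_markers * lens / sum(lens)
  m <- pmax(2L, floor(quota))
  rem <- quota - floor(quota)
  deficit <- n_markers - sum(m)
  if (deficit > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    m[add] <- m[add] + 1L
  } else if (deficit < 0) {
    drop_from <- order(rem)[m[order(rem)] > 2L][seq_len(-deficit)]
    m[drop_from] <- m[drop_from] - 1L
  }
  chrom <- rep(sprintf("chr%02d", seq_len(n_chrom)), m)
  pos <- unlist(lapply(seq_len(n_chrom), function(i) {
    seq(0, lens[i], length.out = m[i])
  }))
  marker <- sprintf("M%03d", seq_len(sum(m)))
  genome_model(chrom, marker, pos)
}

#' @export
print.genome_model <- function(x, ...) {
  lens <- tapply(x$pos_cM, x$chrom, max)
  cat(sprintf("genome_model: %d markers on %d chromosomes (%.1f-%.1f cM)\n",
              nrow(x), length(lens), min(lens), max(lens)))
  invisible(x)
}

#' Read or write a genome model file
#'
#' Delimited text with columns `chrom`, `marker`, `pos_cM`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_genome()` returns a [genome_model()].
#' @export
read_genome <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "marker", "pos_cM")
  if (!all(need %in% names(df))) {
    stop("genome file must have columns: ", paste(need, collapse = ", "))
  }
  genome_model(df$chrom, df$marker, df$pos_cM)
}

#' @rdname read_genome
#' @param genome A [genome_model()].
#' @export
write_genome <- function(genome, path, sep = "\t") {
  utils::write.table(as.data.frame(genome), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split a genome model into per-chromosome marker/position lists
.genome_split <- function(genome) {
  idx <- split(seq_len(nrow(genome)), genome$chrom)
  idx <- idx[unique(genome$chrom)]  # preserve input chromosome order
  lapply(idx, function(i) {
    list(markers = genome$marker[i], pos = genome$pos_cM[i])
  })
}
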