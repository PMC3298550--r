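DNA_BASES <- c("A", "C", "G", "T")

#' Transcript record
#'
#' A transcript sequence with its coding interval. Coordinates are 1-based
#' inclusive on the given sequence; the CDS length must be a multiple of 3.
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence (character or `Biostrings::DNAString`).
#' @param cds_start,cds_end CDS interval, 1-based inclusive.
#' @return Object of class `transcript_record`.
#' @export
transcript_record <- function(id, seq, cds_start, cds_end) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (cds_start < 1 || cds_end > n || cds_end < cds_start) {
    stop("CDS interval outside sequence bounds for transcript ", id)
  }
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("CDS length must be divisible by 3 for transcript ", id)
  }
  structure(list(id = as.character(id), seq = seq,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "transcript_record")
}

#' SNP site
#'
#' A genotyping-assay anchor (extension/flanking) sequence carrying a SNP
#' at a known offset, with the two parental alleles.
#'
#' @param marker Marker id.
#' @param anchor Anchor sequence containing the SNP position.
#' @param offset 1-based offset of the SNP within the anchor.
#' @param allele_p1,allele_p2 The two SNP alleles (distinct single bases).
#' @return Object of class `snp_site`.
#' @export
snp_site <- function(marker, anchor, offset, allele_p1, allele_p2) {
  anchor <- toupper(as.character(anchor))
  offset <- as.integer(offset)
  a1 <- toupper(allele_p1); a2 <- toupper(allele_p2)
  if (offset < 1L || offset > nchar(anchor)) stop("SNP offset outside anchor")
  if (nchar(a1) != 1L || nchar(a2) != 1L || a1 == a2 ||
      !all(c(a1, a2) %in% DNA_BASES)) {
    stop("alleles must be two distinct single bases")
  }
  structure(list(marker = as.character(marker), anchor = anchor,
                 offset = offset, allele_p1 = a1, allele_p2 = a2),
            class = "snp_site")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.comp <- function(base) chartr("ACGT", "TGCA", base)

# all start positions of exact matches of `pattern` in `subject`
.match_starts <- function(pattern, subject) {
  Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                             Biostrings::DNAString(subject)))
}

#' Locate a SNP on a transcript
#'
#' Matches the anchor sequence (with each allele substituted at the SNP
#' offset) exactly against the transcript and its reverse complement. A
#' unique match position is required: no match returns a not-located
#' result; matches at more than one position raise an ambiguity error
#' (silent mis-location would corrupt downstream codon classification).
#'
#' @param transcript A [transcript_record()].
#' @param site A [snp_site()] with anchor length at least 12.
#' @return List with `located` (logical), and when located: `position`
#'   (1-based on the transcript), `strand` (`"+"`/`"-"`), and
#'   `alleles` (the two alleles expressed on the transcript strand,
#'   complemented for `"-"` matches).
#' @export
locate_snp <- function(transcript, site) {
  stopifnot(inherits(transcript, "transcript_record"), inherits(site, "snp_site"))
  if (nchar(site$anchor) < 12L) stop("anchor must be at least 12 nt")
  len <- nchar(site$anchor)
  hits <- list()
  for (allele in c(site$allele_p1, site$allele_p2)) {
    variant <- site$anchor
    substr(variant, site$offset, site$offset) <- allele
    for (s in .match_starts(variant, transcript$seq)) {
      hits[[length(hits) + 1L]] <- c(pos = s + site$offset - 1L, strand = "+")
    }
    for (s in .match_starts(.revcomp(variant), transcript$seq)) {
      hits[[length(hits) + 1L]] <- c(pos = s + len - site$offset, strand = "-")
    }
  }
  if (length(hits) == 0L) return(list(located = FALSE))
  uniq <- unique(do.call(rbind, hits))
  if (nrow(uniq) > 1L) {
    stop("ambiguous anchor location for marker ", site$marker,
         ": matches at ", nrow(uniq), " transcript positions")
  }
  strand <- unname(uniq[1L, "strand"])
  alleles <- c(site$allele_p1, site$allele_p2)
  if (strand == "-") alleles <- .comp(alleles)
  list(located = TRUE, position = as.integer(unname(uniq[1L, "pos"])),
       strand = strand, alleles = alleles)
}

#' Classify the coding effect of a SNP
#'
#' Determines whether a transcript position falls in the coding region and,
#' if so, whether the two alleles are synonymous under the standard genetic
#' code, and how many of the two remaining bases at that codon position
#' would also be synonymous with the P1 codon's amino acid.
#'
#' @param transcript A [transcript_record()].
#' @param position 1-based position on the transcript.
#' @param alleles Character vector of the two alleles on the transcript
#'   strand (P1 first).
#' @return Object of class `snp_annotation`: list with `translated`,
#'   `codons` (the two allele codons, or `NA`), `amino_acids`,
#'   `synonymous` (`NA` when untranslated) and `n_additional_synonymous`
#'   (`NA` when untranslated).
#' @export
classify_effect <- function(transcript, position, alleles) {
  stopifnot(inherits(transcript, "transcript_record"))
  position <- as.integer(position)
  if (position < 1L || position > nchar(transcript$seq)) {
    stop("position outside transcript sequence")
  }
  translated <- position >= transcript$cds_start & position <= transcript$cds_end
  if (!translated) {
    return(structure(list(translated = FALSE, codons = NA_character_,
                          amino_acids = NA_character_, synonymous = NA,
                          n_additional_synonymous = NA_integer_),
                     class = "snp_annotation"))
  }
  off <- position - transcript$cds_start
  codon_start <- transcript$cds_start + (off %/% 3L) * 3L
  codon_pos <- off %% 3L + 1L
  template <- substr(transcript$seq, codon_start, codon_start + 2L)
  mutate <- function(base) {
    cod <- template
    substr(cod, codon_pos, codon_pos) <- base
    cod
  }
  aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])
  codons <- vapply(alleles, mutate, character(1))
  aas <- vapply(codons, aa, character(1))
  others <- setdiff(DNA_BASES, alleles)
  n_add <- sum(vapply(others, function(b) aa(mutate(b)) == aas[1L], logical(1)))
  structure(list(translated = TRUE, codons = unname(codons),
                 amino_acids = unname(aas),
                 synonymous = aas[1L] == aas[2L],
                 n_additional_synonymous = as.integer(n_add)),
            class = "snp_annotation")
}

#' Annotate SNP sites against a transcript set
#'
#' For each site, searches every transcript for a unique anchor match
#' ([locate_snp()]) and classifies the coding effect at the located
#' position ([classify_effect()]). Sites matching more than one transcript
#' are reported as ambiguous and left unclassified.
#'
#' @param sites List of [snp_site()] objects.
#' @param transcripts List of [transcript_record()] objects.
#' @return Data frame with one row per site: `marker`, `located`,
#'   `transcript`, `position`, `strand`, `translated`, `codon_p1`,
#'   `codon_p2`, `aa_p1`, `aa_p2`, `synonymous`, `n_additional_synonymous`,
#'   `note`.
#' @export
annotate_snps <- function(sites, transcripts) {
  rows <- lapply(sites, function(site) {
    row <- data.frame(marker = site$marker, located = FALSE,
                      transcript = NA_character_, position = NA_integer_,
                      strand = NA_character_, translated = NA,
                      codon_p1 = NA_character_, codon_p2 = NA_character_,
                      aa_p1 = NA_character_, aa_p2 = NA_character_,
                      synonymous = NA, n_additional_synonymous = NA_integer_,
                      note = "", stringsAsFactors = FALSE)
    found <- list()
    for (tr in transcripts) {
      loc <- tryCatch(locate_snp(tr, site), error = function(e) e)
      if (inherits(loc, "error")) {
        row$note <- conditionMessage(loc)
        return(row)
      }
      if (loc$located) found[[length(found) + 1L]] <- list(tr = tr, loc = loc)
    }
    if (length(found) == 0L) {
      row$note <- "no transcript match"
      return(row)
    }
    if (length(found) > 1L) {
      row$note <- sprintf("ambiguous: matches %d transcripts", length(found))
      return(row)
    }
    tr <- found[[1L]]$tr; loc <- found[[1L]]$loc
    ann <- classify_effect(tr, loc$position, loc$alleles)
    row$located <- TRUE
    row$transcript <- tr$id
    row$position <- loc$position
    row$strand <- loc$strand
    row$translated <- ann$translated
    if (ann$translated) {
      row$codon_p1 <- ann$codons[1L]; row$codon_p2 <- ann$codons[2L]
      row$aa_p1 <- ann$amino_acids[1L]; row$aa_p2 <- ann$amino_acids[2L]
      row$synonymous <- ann$synonymous
      row$n_additional_synonymous <- ann$n_additional_synonymous
    }
    row
  })
  do.call(rbind, rows)
}

#' Summarize SNP coding-effect annotations
#'
#' @param annotations Data frame from [annotate_snps()].
#' @param digits Rounding for percentages.
#' @return List with counts and percentages: total sites, translated (and
#'   percent of all sites), synonymous among translated, and loci with at
#'   least one additional synonymous allele at the SNP site.
#' @export
summarize_effects <- function(annotations, digits = 0) {
  if (nrow(annotations) == 0L) stop("no annotations to summarize")
  n <- nrow(annotations)
  n_tr <- sum(annotations$translated, na.rm = TRUE)
  n_syn <- sum(annotations$synonymous, na.rm = TRUE)
  n_add <- sum(annotations$n_additional_synonymous >= 1L, na.rm = TRUE)
  list(n_sites = n,
       n_translated = n_tr,
       pct_translated = round(100 * n_tr / n, digits),
       n_synonymous = n_syn,
       pct_synonymous_of_translated =
         if (n_tr > 0) round(100 * n_syn / n_tr, digits) else 0,
       n_with_additional_synonymous = n_add)
}
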