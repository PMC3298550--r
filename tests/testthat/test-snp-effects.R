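# 60 nt fixture transcript: 6 nt 5'UTR, 36 nt CDS (12 codons), 18 nt 3'UTR
FIX_SEQ <- paste0("ACGTAC",
                  "ATGGGAAAACCCTTTGACGGTACTTATCAGTGGTAA",
                  "GCATCGATCCATTGCAGT")
fix_tr <- function() transcript_record("t1", FIX_SEQ, 7, 42)
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("transcript and site constructors validate their inputs", {
  expect_error(transcript_record("t", FIX_SEQ, 7, 41), "divisible by 3")
  expect_error(transcript_record("t", FIX_SEQ, 0, 42), "bounds")
  expect_error(transcript_record("t", FIX_SEQ, 40, 100), "bounds")
  expect_error(snp_site("m", "ACGTACGTACGT", 20, "A", "G"), "offset")
  expect_error(snp_site("m", "ACGTACGTACGT", 3, "A", "A"), "distinct")
  expect_error(snp_site("m", "ACGTACGTACGT", 3, "AG", "C"), "distinct")
})

test_that("anchors locate uniquely on the forward strand", {
  # SNP at transcript position 12 (third base of the Gly codon GGA)
  anchor <- substr(FIX_SEQ, 5, 20)
  site <- snp_site("mGly", anchor, 8, "A", "G")
  loc <- locate_snp(fix_tr(), site)
  expect_true(loc$located)
  expect_equal(loc$position, 12L)
  expect_equal(loc$strand, "+")
  expect_equal(loc$alleles, c("A", "G"))
})

test_that("reverse-complement anchors are located with complemented alleles", {
  anchor_fwd <- substr(FIX_SEQ, 5, 20)
  site_rev <- snp_site("mGlyRev", rc(anchor_fwd), 16 - 8 + 1, "T", "C")
  loc <- locate_snp(fix_tr(), site_rev)
  expect_true(loc$located)
  expect_equal(loc$position, 12L)
  expect_equal(loc$strand, "-")
  expect_equal(loc$alleles, c("A", "G"))  # back on the transcript strand
})

test_that("absent and ambiguous anchors are handled explicitly", {
  absent <- snp_site("mAbs", "TTTTTTTTTTGGGGG", 3, "T", "C")
  expect_false(locate_snp(fix_tr(), absent)$located)

  dup_seq <- paste0(FIX_SEQ, substr(FIX_SEQ, 1, 24))  # 78 nt, CDS intact
  dup_tr <- transcript_record("t2", dup_seq, 7, 42)
  site <- snp_site("mDup", substr(FIX_SEQ, 5, 20), 8, "A", "G")
  expect_error(locate_snp(dup_tr, site), "ambiguous")

  expect_error(locate_snp(fix_tr(), snp_site("mShort", "ACGTACGTACG", 3, "G", "T")),
               "12 nt")
})

test_that("codon classification follows the standard genetic code", {
  tr <- fix_tr()
  # GGA vs GGG: synonymous glycine; GGC and GGT also encode Gly
  gly <- classify_effect(tr, 12, c("A", "G"))
  expect_true(gly$translated)
  expect_equal(gly$codons, c("GGA", "GGG"))
  expect_equal(gly$amino_acids, c("G", "G"))
  expect_true(gly$synonymous)
  expect_equal(gly$n_additional_synonymous, 2L)

  # AAA vs GAA: Lys vs Glu, nonsynonymous, no other base restores Lys
  lys <- classify_effect(tr, 13, c("A", "G"))
  expect_false(lys$synonymous)
  expect_equal(lys$amino_acids, c("K", "E"))
  expect_equal(lys$n_additional_synonymous, 0L)

  # twofold degenerate site: GAC vs GAT both Asp; remaining bases A/G
  # give GAA/GAG (Glu), so no additional synonymous alleles
  asp <- classify_effect(tr, 24, c("C", "T"))
  expect_true(asp$synonymous)
  expect_equal(asp$n_additional_synonymous, 0L)

  # 3' UTR: untranslated, synonymy not applicable
  utr <- classify_effect(tr, 50, c("A", "G"))
  expect_false(utr$translated)
  expect_true(is.na(utr$synonymous))
  expect_true(is.na(utr$n_additional_synonymous))

  expect_error(classify_effect(tr, 0, c("A", "G")), "outside")
  expect_error(classify_effect(tr, 61, c("A", "G")), "outside")
})

test_that("additional synonymous alleles cap at two for a synonymous pair", {
  tr <- fix_tr()
  for (pos in c(9, 12, 15, 18, 21, 24)) {
    base <- substr(FIX_SEQ, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      ann <- classify_effect(tr, pos, c(base, alt))
      if (isTRUE(ann$synonymous)) {
        expect_lte(ann$n_additional_synonymous, 2L)
      }
    }
  }
})

test_that("annotation is invariant to anchor orientation", {
  tr <- fix_tr()
  anchor <- substr(FIX_SEQ, 10, 30)
  fwd <- annotate_snps(list(snp_site("m", anchor, 4, "A", "G")), list(tr))
  revv <- annotate_snps(list(snp_site("m", rc(anchor), 21 - 4 + 1, "T", "C")),
                        list(tr))
  expect_equal(fwd$position, revv$position)
  expect_equal(fwd$synonymous, revv$synonymous)
  expect_equal(fwd$codon_p1, revv$codon_p1)
  expect_equal(fwd$n_additional_synonymous, revv$n_additional_synonymous)
})

test_that("effect summaries match a hand tally", {
  tr <- fix_tr()
  sites <- list(
    snp_site("s1", substr(FIX_SEQ, 5, 20), 8, "A", "G"),   # CDS, synonymous
    snp_site("s2", substr(FIX_SEQ, 8, 20), 6, "A", "G"),   # CDS pos 13, nonsyn
    snp_site("s3", substr(FIX_SEQ, 43, 57), 8, "T", "C"),  # 3' UTR pos 50
    snp_site("s4", substr(FIX_SEQ, 1, 14), 3, "G", "T"),   # 5' UTR pos 3
    snp_site("s5", "GGGGGCCCCCAATT", 7, "C", "T")          # no match
  )
  ann <- annotate_snps(sites, list(tr))
  expect_equal(sum(ann$located), 4L)
  expect_equal(ann$note[ann$marker == "s5"], "no transcript match")
  s <- summarize_effects(ann)
  expect_equal(s$n_sites, 5L)
  expect_equal(s$n_translated, 2L)
  expect_equal(s$pct_translated, 40)
  expect_equal(s$n_synonymous, 1L)
  expect_equal(s$pct_synonymous_of_translated, 50)
  expect_equal(s$n_with_additional_synonymous, 1L)
  expect_error(summarize_effects(ann[0, ]), "no annotations")
})

test_that("transcripts round-trip through FASTA plus CDS table", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">t1 demo transcript", FIX_SEQ), fa)
  cds <- tempfile(fileext = ".tsv")
  writeLines(c("transcript\tcds_start\tcds_end", "t1\t7\t42"), cds)
  trs <- read_transcripts(fa, cds)
  expect_length(trs, 1L)
  expect_equal(trs[["t1"]]$seq, FIX_SEQ)
  expect_equal(trs[["t1"]]$cds_start, 7L)
  # CDS naming a missing transcript is an error
  cds2 <- tempfile(fileext = ".tsv")
  writeLines(c("transcript\tcds_start\tcds_end", "tX\t1\t3"), cds2)
  expect_error(read_transcripts(fa, cds2), "absent")
})
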