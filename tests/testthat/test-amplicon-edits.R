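# A 200-bp amplicon with a 21-nt in-frame target carrying Tyr (TAC) and
# adjacent Leu-Ser (CTG-TCG) codons, mirroring the validated single-edit
# (Y -> C) and co-edit (L -> P with S -> P) outcome classes.
make_test_amplicon <- function() {
  set.seed(8123)
  target <- paste0("GCT", "TAC", "GGT", "CTG", "TCG", "GAA", "CAT")  # 21 nt
  left <- random_flank(90)
  right <- random_flank(89)
  ref <- paste0(left, target, right)
  amplicon_spec(ref, 90, 90 + 21, cds_strand = "+", frame_offset = 0,
                residues = data.frame(protein_pos = 510L, aa = "A",
                                      codon_start = 0L))
}

test_that("perfect pairs reconstruct the reference and bad overlaps are dropped", {
  spec <- make_test_amplicon()
  ref <- spec$reference
  L <- nchar(ref)
  r1 <- substr(ref, 1, 120)
  r2 <- revcomp(substr(ref, L - 120 + 1, L))
  pair <- merge_pairs(list(seq = r1, qual = strrep("I", 120)),
                      list(seq = r2, qual = strrep("I", 120)))
  expect_equal(pair$seq, ref)
  expect_equal(pair$n_dropped, 0L)
  # non-overlapping mates are dropped and tallied
  none <- merge_pairs(list(seq = substr(ref, 1, 50), qual = strrep("I", 50)),
                      list(seq = revcomp(substr(ref, 150, 199)),
                           qual = strrep("I", 50)))
  expect_equal(length(none$seq), 0L)
  expect_equal(none$n_dropped, 1L)
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  spec <- make_test_amplicon()
  ref <- spec$reference
  L <- nchar(ref)
  r1 <- substr(ref, 1, 120)
  r2_seq <- substr(ref, L - 120 + 1, L)
  # plant a disagreement at reference position 100 (inside the overlap)
  pos_in_r1 <- 100
  pos_in_r2 <- 100 - (L - 120)
  truth_base <- substr(ref, 100, 100)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  substr(r1, pos_in_r1, pos_in_r1) <- wrong
  q1 <- strrep("I", 120)
  substr(q1, pos_in_r1, pos_in_r1) <- "#"  # low quality on the wrong base
  m <- merge_pairs(list(seq = r1, qual = q1),
                   list(seq = revcomp(r2_seq), qual = strrep("I", 120)))
  expect_equal(substr(m$seq, 100, 100), truth_base)
  # flip the qualities: the wrong base wins instead
  q2 <- strrep("I", 120)
  substr(q2, 120 - pos_in_r2 + 1, 120 - pos_in_r2 + 1) <- "#"
  m2 <- merge_pairs(list(seq = r1, qual = strrep("I", 120)),
                    list(seq = revcomp(r2_seq), qual = q2))
  expect_equal(substr(m2$seq, 100, 100), wrong)
})

test_that("locate_target honours the flank-mismatch threshold and ambiguity rule", {
  spec <- make_test_amplicon()
  target <- target_ref <- substr(spec$reference, 91, 111)
  read <- paste0("ACGT", spec$flank5, target, spec$flank3, "TTAA")
  expect_equal(locate_target(read, spec), target)
  # missing 3' flank
  expect_true(is.na(locate_target(paste0("ACGT", spec$flank5, target), spec)))
  # one mismatch in the 5' flank: found at 1 allowed mismatch, not at 0
  f5_mut <- spec$flank5
  substr(f5_mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(f5_mut, 3, 3))[1]
  read_mm <- paste0("ACGT", f5_mut, target, spec$flank3)
  expect_equal(locate_target(read_mm, spec, max_flank_mismatch = 1), target)
  expect_true(is.na(locate_target(read_mm, spec, max_flank_mismatch = 0)))
  # reverse-complemented reads are recovered in RC-aware mode
  expect_equal(locate_target(revcomp(read), spec, try_revcomp = TRUE), target)
  expect_true(is.na(locate_target(revcomp(read), spec)))
})

test_that("base composition recovers planted per-position rates", {
  spec <- make_test_amplicon()
  tlen <- 21
  rates <- numeric(tlen)
  rates[5] <- 0.30  # the Tyr codon adenine (TAC position 2 of codon 2)
  sim <- simulate_amplicon_reads(spec, edit_rates = rates, error_rate = 0.001,
                                 n_reads = 20000, seed = 61)
  prof <- base_composition(sim$reads, spec)
  comp <- prof$composition
  expect_lt(abs(comp$fG[5] - 0.30), 0.01)
  # positions sum to one where covered
  expect_equal(rowSums(comp[, c("fA", "fC", "fG", "fT")]),
               rep(1, tlen), tolerance = 1e-9)
  # editing efficiency equals the G fraction at reference adenines
  eff <- editing_efficiency(prof)
  expect_equal(eff[5], comp$fG[5])
  expect_true(is.na(eff[comp$ref == "G"][1]))
  # invariance to read order and duplication
  prof2 <- base_composition(rev(sim$reads), spec)
  expect_equal(prof2$composition, comp)
  prof3 <- base_composition(c(sim$reads, sim$reads), spec)
  expect_equal(prof3$composition$fG, comp$fG)
})

test_that("pure reference reads give fraction one at every reference base", {
  spec <- make_test_amplicon()
  sim <- simulate_amplicon_reads(spec, error_rate = 0, n_reads = 200, seed = 62)
  prof <- base_composition(sim$reads, spec)
  comp <- prof$composition
  for (b in c("A", "C", "G", "T")) {
    expect_equal(comp[[paste0("f", b)]][comp$ref == b],
                 rep(1, sum(comp$ref == b)))
  }
})

test_that("amino-acid outcomes label single edits, co-edits, WT and indels", {
  spec <- make_test_amplicon()
  target <- target_reference(spec)
  # Y511C: TAC -> TGC (codon 2 of the target, protein 511 via the anchor)
  hap_y <- target
  substr(hap_y, 5, 5) <- "G"
  # co-edit: CTG -> CCG (L513P) and TCG -> CCG (S514P)
  hap_ls <- target
  substr(hap_ls, 11, 11) <- "C"
  substr(hap_ls, 13, 13) <- "C"
  sim <- simulate_amplicon_reads(
    spec, haplotypes = c(structure(c(0.4, 0.2), names = c(hap_y, hap_ls))),
    error_rate = 0, n_reads = 5000, seed = 63
  )
  prof <- call_aa_outcomes(base_composition(sim$reads, spec), spec)
  at <- prof$allele_table
  expect_equal(at$aa_outcome[at$haplotype == hap_y], "Y511C")
  expect_equal(at$aa_outcome[at$haplotype == hap_ls], "L513P/S514P")
  expect_equal(at$aa_outcome[at$haplotype == target], "WT")
  expect_equal(at$fraction[at$haplotype == target],
               1 - at$fraction[at$haplotype == hap_y] -
                 at$fraction[at$haplotype == hap_ls])
  # synonymous and indel labels
  expect_equal(label_outcome_for_test(spec, replace_at(target, 21, "C")),
               "synonymous")  # CAT -> CAC, both His
  expect_equal(label_outcome_for_test(spec, substr(target, 1, 20)), "indel")
})

test_that("antisense-strand amplicons translate through the reverse complement", {
  # same coding content presented on the opposite sequencing strand
  fwd <- make_test_amplicon()
  ref_rc <- revcomp(fwd$reference)
  L <- nchar(fwd$reference)
  spec_rc <- amplicon_spec(ref_rc, L - 111, L - 90, cds_strand = "-",
                           frame_offset = 0,
                           residues = data.frame(protein_pos = 510L, aa = "A",
                                                 codon_start = 0L))
  target_rc <- target_reference(spec_rc)
  expect_equal(revcomp(target_rc), target_reference(fwd))
  # the Y511C haplotype seen on this strand: A->G on coding = T->C here
  hap <- target_rc
  pos <- 21 - 5 + 1
  expect_equal(substr(hap, pos, pos), "T")
  substr(hap, pos, pos) <- "C"
  prof <- base_composition(rep(c(target_rc, hap), c(6, 4)), spec_rc,
                           located = TRUE)
  prof <- call_aa_outcomes(prof, spec_rc)
  at <- prof$allele_table
  expect_equal(at$aa_outcome[at$haplotype == hap], "Y511C")
})

test_that("haplotype fractions are recovered at deep coverage", {
  spec <- make_test_amplicon()
  target <- target_reference(spec)
  hap <- replace_at(replace_at(target, 11, "C"), 13, "C")
  sim <- simulate_amplicon_reads(spec, haplotypes = setNames(0.4, hap),
                                 error_rate = 0.001, n_reads = 50000, seed = 64)
  prof <- base_composition(sim$reads, spec)
  at <- prof$allele_table
  expect_equal(at$fraction[at$haplotype == hap], 0.4, tolerance = 0.0375)
  expect_lt(abs(at$fraction[at$haplotype == hap] - 0.4), 0.015)
})

test_that("simulation input validation rejects impossible configurations", {
  spec <- make_test_amplicon()
  expect_error(simulate_amplicon_reads(spec, edit_rates = rep(0.5, 21)),
               "neither A nor T")
  bad_haps <- setNames(c(0.7, 0.6), c(target_reference(spec),
                                      target_reference(spec)))
  expect_error(simulate_amplicon_reads(spec, haplotypes = bad_haps),
               "more than 1")
})
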