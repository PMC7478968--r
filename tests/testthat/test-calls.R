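edit_df <- function(kind, position, ref_allele = "", alt_allele = "") {
  data.frame(kind = kind, position = position, ref_allele = ref_allele,
             alt_allele = alt_allele, stringsAsFactors = FALSE)
}

test_that("net frame shift sums indel lengths and ignores substitutions", {
  expect_equal(net_frame_shift(edit_df("insertion", 5,
                                       alt_allele = "ACGTACGTACGT")), 12L)
  expect_equal(net_frame_shift(edit_df("deletion", 5,
                                       ref_allele = random_dna(22))), -22L)
  expect_equal(net_frame_shift(NULL), 0L)
  expect_equal(net_frame_shift(edit_df(character(), integer(),
                                       character(), character())), 0L)
  mixed <- rbind(edit_df("insertion", 5, alt_allele = "AC"),
                 edit_df("deletion", 9, ref_allele = "TTT"),
                 edit_df("substitution", 20, "G", "T"))
  expect_equal(net_frame_shift(mixed), -1L)
})

test_that("frame classes follow the non-negative residue of net indel mod 3", {
  expect_equal(classify_allele(edit_df("deletion", 5,
                                       ref_allele = "ACGT"))$frame_class,
               "frameshift_plus2")   # -4 = 3n+2
  expect_equal(classify_allele(edit_df("deletion", 5,
                                       ref_allele = "ACGTAC"))$frame_class,
               "in_frame")           # -6 = 3n
  expect_equal(classify_allele(edit_df("insertion", 5,
                                       alt_allele = "ACGTACG"))$frame_class,
               "frameshift_plus1")   # +7 = 3n+1
  sub_only <- classify_allele(edit_df("substitution", 5, "A", "G"))
  expect_equal(sub_only$frame_class, "in_frame")
  expect_equal(sub_only$net_indel, 0L)
  expect_equal(sub_only$n_substitutions, 1L)
  expect_equal(classify_allele(NULL)$frame_class, "WT")
})

test_that("classification is invariant to edit order and to normalization shifts", {
  set.seed(31)
  for (i in 1:6) {
    n_ed <- sample(2:4, 1)
    edits <- do.call(rbind, lapply(seq_len(n_ed), function(j) {
      k <- sample(c("insertion", "deletion", "substitution"), 1)
      edit_df(k, 10 * j,
              ref_allele = if (k != "insertion") random_dna(sample(1:5, 1)) else "",
              alt_allele = if (k != "deletion")
                random_dna(if (k == "substitution") 1 else sample(1:5, 1)) else "")
    }))
    edits$ref_allele[edits$kind == "substitution"] <-
      vapply(nchar(edits$alt_allele[edits$kind == "substitution"]),
             random_dna, "")
    shuffled <- edits[sample(nrow(edits)), ]
    expect_equal(classify_allele(shuffled)$frame_class,
                 classify_allele(edits)$frame_class)
  }
})

test_that("an in-frame substitution creating a stop codon is flagged stop-gain", {
  # ORF: ATG GCA GCT GGT CCC, no reference stop
  ref <- reference_target("toy", "ATGGCAGCTGGTCCC", 0, 15)
  sub <- edit_df("substitution", 6, "GCT", "TAA")
  cls <- classify_allele(sub, ref)
  expect_equal(cls$frame_class, "in_frame")
  expect_true(cls$stop_gain)
  # frameshifts never carry the flag even though a downstream stop is implied
  del1 <- edit_df("deletion", 6, ref_allele = "G")
  expect_false(classify_allele(del1, ref)$stop_gain)
})

test_that("in-frame codon-aligned deletion removes exactly one residue", {
  ref <- reference_target("toy", "ATGGCAGCTGGTCCC", 0, 15)
  tr <- translate_allele(ref, edit_df("deletion", 6, ref_allele = "GCT"))
  expect_equal(tr$ref_protein, "MAAGP")
  expect_equal(tr$protein, "MAGP")
})

test_that("in-frame mid-codon insertion adds one residue with at most two flanking substitutions", {
  ref <- reference_target("toy", "ATGGCAGCTGGTCCC", 0, 15)
  tr <- translate_allele(ref, edit_df("insertion", 7, alt_allele = "AAA"))
  expect_equal(nchar(tr$protein), nchar(tr$ref_protein) + 1L)
  # residues outside the edited codon neighbourhood are untouched
  expect_equal(substr(tr$protein, 1, 2), substr(tr$ref_protein, 1, 2))
  expect_equal(substr(tr$protein, nchar(tr$protein) - 1, nchar(tr$protein)),
               substr(tr$ref_protein, nchar(tr$ref_protein) - 1,
                      nchar(tr$ref_protein)))
})

test_that("frameshift translation diverges and truncates at the first stop", {
  ref <- reference_target("toy", "ATGGCAGCTGGTCCCTAA", 0, 18)
  tr <- translate_allele(ref, edit_df("deletion", 6, ref_allele = "G"))
  # independent oracle: translate the manually edited sequence
  mut <- paste0(substr(ref$sequence, 1, 6), substr(ref$sequence, 8, 18))
  expected <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mut, 1, 3 * (nchar(mut) %/% 3)))))
  expected <- sub("(\\*).*$", "\\1", expected)
  expect_equal(tr$protein, expected)
  expect_false(tr$protein == tr$ref_protein)
})

test_that("protein length change of stop-free in-frame alleles is net/3", {
  set.seed(32)
  tt <- make_toy_target(total = 120L)
  for (net in c(-6L, -3L, 3L, 6L)) {
    cut <- tt$site$cut_index
    edits <- if (net < 0)
      edit_df("deletion", cut, ref_allele = substr(tt$ref$sequence, cut + 1,
                                                   cut - net)) else
      edit_df("insertion", cut, alt_allele = random_dna(net))
    cls <- classify_allele(edits, tt$ref, tt$site)
    if (isTRUE(cls$stop_gain)) next
    tr <- translate_allele(tt$ref, edits, tt$site)
    expect_equal(nchar(tr$protein) - nchar(tr$ref_protein), net / 3)
  }
})

test_that("identical clones collapse into one event, distinct clones never do", {
  base <- rbind(
    cbind(edit_df("insertion", 57, alt_allele = "AT"), clone_id = "a"),
    cbind(edit_df("insertion", 57, alt_allele = "AT"), clone_id = "b"),
    cbind(edit_df("insertion", 57, alt_allele = "AT"), clone_id = "c"))
  calls <- calls_from_variants(base)
  ev <- collapse_events(calls)
  expect_equal(ev$summary$n_edited, 3L)
  expect_equal(ev$summary$n_events, 1L)
  expect_equal(ev$events$n_clones, 3L)

  distinct <- rbind(
    cbind(edit_df("insertion", 57, alt_allele = "AT"), clone_id = "a"),
    cbind(edit_df("insertion", 57, alt_allele = "GC"), clone_id = "b"),
    cbind(edit_df("deletion", 57, ref_allele = "T"), clone_id = "c"))
  ev2 <- collapse_events(calls_from_variants(distinct))
  expect_equal(ev2$summary$n_events, ev2$summary$n_edited)
})

test_that("clone counts are conserved across statuses for every bundled dataset", {
  for (n in c("grlB", "grlC", "KIF1A", "fAR1", "Dync1li1_sg1",
              "Dync1li1_sg2", "Dync1li1_combined")) {
    calls <- example_calls(n)
    s <- collapse_events(calls)$summary
    expect_equal(s$n_clones, s$n_failed + s$n_sequenced, info = n)
    expect_equal(s$n_sequenced, s$n_wt + s$n_edited, info = n)
    expect_lte(s$n_events, s$n_edited)
    expect_equal(sum(s$event_class_counts[c("in_frame", "frameshift_plus1",
                                            "frameshift_plus2")]),
                 s$n_events, info = n)
  }
})

test_that("FASTA alignment path and variant-table path agree on the grlB dataset", {
  ex <- crispr_e_example("grlB")
  ref <- read_reference(ex$reference, 0, 180)
  site <- find_target_site(ref, ex$guide)
  status <- utils::read.delim(ex$status)
  cl <- read_clones(ex$clones)
  calls_fa <- call_alleles(ref, cl$sequences, site, status = status)
  calls_tv <- calls_from_variants(ex$variants, ref = ref, site = site)
  sfa <- collapse_events(calls_fa)$summary
  stv <- collapse_events(calls_tv)$summary
  expect_equal(sfa$event_class_counts, stv$event_class_counts)
  expect_equal(sfa$n_events, stv$n_events)
  expect_equal(sfa$n_failed, stv$n_failed)
})
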