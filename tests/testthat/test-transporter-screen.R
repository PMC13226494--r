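hits3 <- tibble::tibble(
  query_id = "q", subject_id = c("s1", "s2", "s3"),
  bit_score = c(99, 100, 101), family_hint = "MFS", genome = "A"
)

test_that("bit-score retention is strictly greater-than", {
  kept <- filter_by_bitscore(hits3)
  expect_equal(kept$subject_id, "s3")
  expect_equal(nrow(filter_by_bitscore(hits3[0, ])), 0)
  expect_equal(nrow(filter_by_bitscore(hits3, threshold = -Inf)), 3)
})

test_that("topology filters encode the family helix-count rules", {
  topo <- tibble::tibble(
    seq_id = paste0("s", 1:6), tm_helix_count = c(12, 11, 6, 5, 3, 13),
    has_signal_peptide = FALSE, length_aa = 400
  )
  expect_equal(filter_by_topology(topo, "MFS")$seq_id, "s1")
  expect_equal(filter_by_topology(topo, "NCS1")$seq_id, "s1")
  expect_setequal(filter_by_topology(topo, "ABC_TM")$seq_id, c("s3", "s5"))
  expect_equal(nrow(filter_by_topology(topo[0, ], "MFS")), 0)
  expect_error(filter_by_topology(topo, "PTS"), "no topology rule")
})

test_that("retention filters commute and are idempotent", {
  topo <- tibble::tibble(
    seq_id = hits3$subject_id, tm_helix_count = c(12, 12, 11),
    has_signal_peptide = FALSE, length_aa = 420
  )
  with_topo <- dplyr::left_join(hits3, topo, by = c(subject_id = "seq_id"))
  a <- filter_by_topology(filter_by_bitscore(with_topo, 98), "MFS")
  b <- filter_by_bitscore(filter_by_topology(with_topo, "MFS"), 98)
  expect_equal(a, b)
  expect_equal(filter_by_bitscore(filter_by_bitscore(hits3)),
               filter_by_bitscore(hits3))
})

test_that("BBH calls mutual unique best hits only", {
  one <- tibble::tibble(query_id = "a1", subject_id = "b1", bit_score = 50)
  rev1 <- tibble::tibble(query_id = "b1", subject_id = "a1", bit_score = 48)
  expect_equal(bbh_orthologs(one, rev1)$seq_a, "a1")

  # a tie in one direction voids the call
  tie <- tibble::tibble(query_id = c("a1", "a1"),
                        subject_id = c("b1", "b2"), bit_score = c(50, 50))
  rev2 <- tibble::tibble(query_id = c("b1", "b2"),
                         subject_id = c("a1", "a1"), bit_score = c(40, 30))
  expect_equal(nrow(bbh_orthologs(tie, rev2)), 0)
})

test_that("BBH equals the brute-force mutual-best scan on random matrices", {
  set.seed(71)
  for (k in 1:10) {
    na <- sample(3:7, 1)
    nb <- sample(3:7, 1)
    A <- paste0("a", seq_len(na))
    B <- paste0("b", seq_len(nb))
    # coarse integer scores make ties likely
    mab <- matrix(sample(1:12, na * nb, replace = TRUE), na, nb,
                  dimnames = list(A, B))
    mba <- matrix(sample(1:12, na * nb, replace = TRUE), nb, na,
                  dimnames = list(B, A))
    long <- function(m) {
      tibble::tibble(query_id = rep(rownames(m), ncol(m)),
                     subject_id = rep(colnames(m), each = nrow(m)),
                     bit_score = as.vector(m))
    }
    got <- bbh_orthologs(long(mab), long(mba))
    want <- oracle_bbh(mab, mba)
    expect_equal(got$seq_a, want$seq_a)
    expect_equal(got$seq_b, want$seq_b)
  }
})

test_that("BBH is symmetric under swapping the two genomes", {
  ab <- read_score_table(fixture_path("synthetic_mfs_scores_ab.tsv"))
  ba <- read_score_table(fixture_path("synthetic_mfs_scores_ba.tsv"))
  fwd <- bbh_orthologs(ab, ba)
  rev <- bbh_orthologs(ba, ab)
  expect_equal(fwd$seq_a, sort(rev$seq_b))
  expect_equal(nrow(fwd), 4)
})

test_that("operons classify into CUT-1 / CUT-2 by TM gene count", {
  cut1 <- tibble::tibble(seq_id = c("p1", "p2", "p3"),
                         role = c("SBP", "TM", "TM"))
  expect_equal(classify_cut_subfamily(cut1, genome_has_shared_nbp = TRUE),
               "CUT-1")
  # without any NBP, in operon or shared, the system is incomplete
  expect_equal(classify_cut_subfamily(cut1, genome_has_shared_nbp = FALSE),
               "incomplete")
  cut2 <- tibble::tibble(seq_id = c("q1", "q2", "q3"),
                         role = c("NBP", "SBP", "TM"))
  expect_equal(classify_cut_subfamily(cut2), "CUT-2")
  expect_equal(classify_cut_subfamily(tibble::tibble(seq_id = "x",
                                                     role = "SBP")),
               "incomplete")
})

test_that("the packaged survey fixture reproduces the published inventory", {
  inv <- screen_transporters(
    fixture_path("synthetic_hits.tsv"),
    fixture_path("synthetic_topology.tsv"),
    fixture_path("synthetic_operons.tsv"),
    fixture_path("synthetic_mfs_scores_ab.tsv"),
    fixture_path("synthetic_mfs_scores_ba.tsv")
  )
  counts <- tidyr::pivot_wider(inv$counts, names_from = "family",
                               values_from = "n_systems", values_fill = 0L)
  acid <- counts[counts$genome == "S_acidophilus", ]
  thermo <- counts[counts$genome == "S_thermosulfidooxidans", ]
  expect_equal(acid$MFS, 8)
  expect_equal(thermo$MFS, 8)
  expect_equal(acid[["CUT-1"]], 5)
  expect_equal(thermo[["CUT-1"]], 5)
  expect_equal(acid[["CUT-2"]], 3)
  expect_equal(thermo[["CUT-2"]], 3)
  expect_equal(acid$PTS, 1)
  expect_equal(thermo$PTS, 0)
  expect_equal(acid[["NCS-1"]], 7)
  expect_equal(thermo[["NCS-1"]], 10)
  expect_equal(nrow(inv$orthologs), 4)
  expect_setequal(inv$orthologs$seq_a,
                  c("AEW04366.1", "AEW06192.1", "AEW06836.1", "AEW06866.1"))

  # decoys: sub-threshold, boundary and wrong-topology sequences are absent
  expect_false(any(c("AEW07777.1", "SMC07777.1", "AEW07778.1", "SMC07778.1")
                   %in% inv$members$seq_id))
  # incomplete Dha-like PTS homologs contribute no system
  expect_false(any(grepl("SMC091", inv$members$seq_id)))
})

test_that("substrate annotation is carried through, not inferred", {
  inv <- screen_transporters(
    fixture_path("synthetic_hits.tsv"),
    fixture_path("synthetic_topology.tsv"),
    fixture_path("synthetic_operons.tsv")
  )
  sys <- inv$systems
  expect_equal(sys$substrate[sys$system_id == "sa_cut2_rib"], "ribose")
  expect_equal(sys$substrate[sys$system_id == "sa_pts_fru"], "fructose")
  expect_true(is.na(sys$substrate[sys$system_id == "sa_cut1_u1"]))
})

test_that("dangling operon members raise an error naming them", {
  hits <- tibble::tibble(query_id = "q", subject_id = "s1", bit_score = 200,
                         family_hint = "ABC_SBP", genome = "A")
  topo <- tibble::tibble(seq_id = "s1", tm_helix_count = 1,
                         has_signal_peptide = TRUE, length_aa = 400)
  ops <- tibble::tibble(operon_id = "op1", seq_id = c("s1", "ghost1"),
                        role = c("SBP", "TM"), genome = "A",
                        substrate = NA_character_)
  expect_error(assemble_inventory(hits, topo, ops), "ghost1")
})

test_that("empty inputs give an empty inventory", {
  inv <- assemble_inventory(
    hits3[0, ],
    tibble::tibble(seq_id = character(0), tm_helix_count = integer(0),
                   has_signal_peptide = logical(0), length_aa = integer(0)),
    tibble::tibble(operon_id = character(0), seq_id = character(0),
                   role = character(0), genome = character(0),
                   substrate = character(0))
  )
  expect_equal(nrow(inv$systems), 0)
  expect_equal(nrow(inv$counts), 0)
  expect_equal(nrow(inv$orthologs), 0)
})

test_that("inventories serialize to JSON and per-family TSVs", {
  out_json <- withr::local_tempfile(fileext = ".json")
  out_dir <- withr::local_tempdir()
  inv <- screen_transporters(
    fixture_path("synthetic_hits.tsv"),
    fixture_path("synthetic_topology.tsv"),
    fixture_path("synthetic_operons.tsv")
  )
  write_inventory(inv, out_json, out_dir)
  parsed <- jsonlite::read_json(out_json)
  expect_named(parsed, c("counts", "systems", "orthologs"))
  expect_true(file.exists(file.path(out_dir, "MFS.tsv")))
  expect_s3_class(tidy(inv), "tbl_df")
})
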