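fx_dir <- withr::local_tempdir(.local_envir = teardown_env())
fx <- make_xlink_fixture(dir = fx_dir)

test_that("read_crosslinks derives kind and flags non-linkable residues", {
  records <- read_crosslinks(fx$links_path)
  intra <- records[records$protein_a == "FAN1" & records$res_a == 539, ]
  expect_true(all(intra$kind == "intra"))
  inter <- records[records$protein_b == "MLH1" & records$res_a == 146, ]
  expect_true(all(inter$kind == "inter"))
  # N-terminal methionine is linkable without warning
  expect_true(any(records$res_a == 1L & records$letter_a == "M"))
  # a G at a non-terminal position draws a validation warning
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("protein1", "residue1", "letter1", "protein2",
                     "residue2", "letter2", "score", sep = "\t"),
               paste("A", 5, "G", "B", 9, "K", 25, sep = "\t")), path)
  expect_warning(read_crosslinks(path), "crosslinkable")
  writeLines(c("protein1\tresidue1", "A\t5"), path)
  expect_error(read_crosslinks(path), "missing column")
})

test_that("filter_by_score is strict, idempotent and identity at -Inf", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("protein1", "residue1", "letter1", "protein2",
                     "residue2", "letter2", "score", sep = "\t"),
               paste("A", 1, "K", "B", 2, "K", 19.9, sep = "\t"),
               paste("A", 3, "K", "B", 4, "K", 20.0, sep = "\t"),
               paste("A", 5, "K", "B", 6, "K", 20.1, sep = "\t")), path)
  records <- read_crosslinks(path)
  kept <- filter_by_score(records)
  expect_equal(kept$score, 20.1) # only strictly above 20
  expect_equal(filter_by_score(kept), kept)
  expect_equal(nrow(filter_by_score(records[0, ])), 0L)
  expect_equal(nrow(filter_by_score(records, -Inf)), nrow(records))
})

test_that("count_pairs counts unique unordered residue pairs", {
  records <- filter_by_score(read_crosslinks(fx$links_path))
  counts <- count_pairs(records)
  get <- function(a, b) counts$n_links[counts$protein_a == a &
                                         counts$protein_b == b]
  expect_equal(get("FAN1", "MLH1"), 3L) # duplicate record counted once
  expect_equal(get("FAN1", "PMS2"), 6L)
  expect_equal(get("FAN1", "FAN1"), 1L)
  # invariance to record order and protein_a/protein_b swap
  shuffled <- records[sample(nrow(records)), ]
  expect_equal(count_pairs(shuffled), counts)
  swapped <- records
  swapped[, c("protein_a", "res_a", "letter_a",
              "protein_b", "res_b", "letter_b")] <-
    swapped[, c("protein_b", "res_b", "letter_b",
                "protein_a", "res_a", "letter_a")]
  expect_equal(count_pairs(swapped), counts)
  expect_equal(nrow(count_pairs(records[0, ])), 0L)
})

test_that("map_distance resolves, is symmetric, and reports unresolved residues", {
  stru <- read_structure(fx$structure_path)
  m <- structure_map(chains = c(P1 = "A", P2 = "B"))
  d <- map_distance(list(protein_a = "P1", res_a = 10,
                         protein_b = "P1", res_b = 20), stru, m)
  expect_equal(d$distance, 5.0)
  expect_equal(d$status, "resolved")
  rev <- map_distance(list(protein_a = "P1", res_a = 20,
                           protein_b = "P1", res_b = 10), stru, m)
  expect_equal(rev$distance, d$distance)
  # residue absent from the model: unresolved, not an error
  un <- map_distance(list(protein_a = "P1", res_a = 999,
                          protein_b = "P1", res_b = 10), stru, m)
  expect_true(is.na(un$distance))
  expect_equal(un$status, "unresolved")
  expect_error(map_distance(list(protein_a = "NOPE", res_a = 1,
                                 protein_b = "P1", res_b = 10), stru, m),
               "chain assignment")
  # numbering offset: sequence position 5 -> structure residue 10
  m_off <- structure_map(chains = c(P1 = "A"), offsets = c(P1 = 5L))
  d_off <- map_distance(list(protein_a = "P1", res_a = 5,
                             protein_b = "P1", res_b = 15), stru, m_off)
  expect_equal(d_off$distance, 5.0)
})

test_that("distances are invariant under rigid-body transforms", {
  stru <- read_structure(fx$structure_path)
  m <- structure_map(chains = c(P1 = "A", P2 = "B"))
  rec <- list(protein_a = "P1", res_a = 10, protein_b = "P2", res_b = 40)
  d0 <- map_distance(rec, stru, m)$distance
  set.seed(17)
  for (i in 1:10) {
    moved <- rigid_transform(stru)
    expect_equal(map_distance(rec, moved, m)$distance, d0,
                 tolerance = 1e-9)
  }
})

test_that("the PDB writer/reader round-trips and the mmCIF path agrees", {
  stru <- read_structure(fx$structure_path)
  expect_equal(stru$resid, fx$coords$resid)
  expect_equal(stru$x, fx$coords$x, tolerance = 1e-3)
  # same coordinates expressed as a minimal mmCIF atom_site loop
  cif <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "auth_atom_id", "auth_comp_id",
                    "auth_asym_id", "auth_seq_id", "Cartn_x", "Cartn_y",
                    "Cartn_z")))
  body <- sprintf("ATOM %d CA %s %s %d %.3f %.3f %.3f",
                  seq_len(nrow(fx$coords)), fx$coords$resname,
                  fx$coords$chain, fx$coords$resid, fx$coords$x,
                  fx$coords$y, fx$coords$z)
  writeLines(c(hdr, body, "#"), cif)
  stru_cif <- read_structure(cif)
  expect_equal(stru_cif$resid, stru$resid)
  expect_equal(stru_cif$x, stru$x, tolerance = 1e-3)
  expect_equal(stru_cif$chain, stru$chain)
})

test_that("flag_consistency uses an inclusive 30 A cutoff", {
  expect_true(flag_consistency(27))
  expect_true(flag_consistency(30.0))
  expect_false(flag_consistency(45))
  expect_equal(flag_consistency(c(5, 31)), c(TRUE, FALSE))
})

test_that("map_distances annotates a filtered crosslink table", {
  stru <- read_structure(fx$structure_path)
  m <- structure_map(chains = c(FAN1 = "A", MLH1 = "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("protein1", "residue1", "letter1", "protein2",
                     "residue2", "letter2", "score", sep = "\t"),
               paste("FAN1", 10, "K", "FAN1", 20, "S", 25, sep = "\t"),
               paste("FAN1", 10, "K", "MLH1", 40, "Y", 25, sep = "\t"),
               paste("FAN1", 10, "K", "MLH1", 999, "K", 25, sep = "\t")),
             path)
  out <- map_distances(read_crosslinks(path), stru, m)
  expect_equal(out$distance[1], 5.0)
  expect_true(out$consistent[1])
  expect_true(is.na(out$distance[3]) && is.na(out$consistent[3]))
})

test_that("consensus_profile follows the strict >80% highlight rule", {
  aln <- c("SYAAG", "SYTC-", "SYTAG", "SYTCG", "SFTAG")
  prof <- consensus_profile(aln)
  expect_equal(prof$residue[1], "S")
  expect_equal(prof$fraction[1], 1.0)
  expect_equal(prof$residue[2], "Y")
  expect_equal(prof$fraction[2], 0.8) # 4 of 5
  expect_equal(prof$fraction[3], 4 / 5) # A,T,T,T,T
  expect_equal(prof$fraction[4], 3 / 5) # A,C,A,C,A
  # gaps leave the denominator: column 5 has 4 non-gap rows, all G
  expect_equal(prof$fraction[5], 1.0)
  expect_equal(prof$n_nongap[5], 4L)
  hl <- highlight_consensus(prof, 0.80)
  expect_true(1 %in% hl)
  expect_false(2 %in% hl) # exactly 0.8 is NOT highlighted (strict >)
  expect_true(5 %in% hl)
  gap_col <- consensus_profile(c("A-", "C-"))
  expect_true(is.na(gap_col$residue[2]))
  expect_false(2 %in% highlight_consensus(gap_col))
  expect_error(consensus_profile(c("AA", "AAA")), "ragged")
  expect_error(consensus_profile("AA"), ">= 2 sequences")
})

test_that("find_motif reports all 1-based (overlapping) hits", {
  seq_fa <- read_fasta(system.file("extdata", "fan1_nterm_synthetic.fasta",
                                   package = "repeatlens"))
  expect_equal(find_motif(seq_fa[[1]], "SPYF"), 126L)
  expect_equal(find_motif("AAAA", "QQ"), integer())
  expect_equal(find_motif("SPYFAAA", "SPYF"), 1L)
  expect_equal(find_motif("ststs", "STS"), c(1L, 3L)) # overlaps, case-folded
  expect_error(find_motif("AAAA", ""), "non-empty")
})

test_that("span_length is inclusive 1-based arithmetic", {
  expect_equal(span_length(118, 177), 60L)
  expect_equal(span_length(126, 129), 4L)
  expect_equal(span_length(7, 7), 1L)
  expect_error(span_length(10, 9), "start <= end")
  expect_error(span_length(0, 9), "start")
})
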