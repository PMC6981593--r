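test_that("FASTA reading normalises case, tokenises ids, preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 first protein", "acde",
               ">P2", "MKT", "AYI"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(P1 = "ACDE", P2 = "MKTAYI"))
})

test_that("FASTA write/read round-trips arbitrary record sets", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(1:8, 1)
    seqs <- vapply(seq_len(n), function(i) random_seq(sample(1:90, 1)),
                   character(1))
    names(seqs) <- paste0("SEQ", seq_len(n))
    f <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(seqs, f)
    expect_identical(read_fasta(f), seqs)
  }
})

test_that("duplicate ids and empty sequences are hard errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "ACDE", ">P1", "MKT"), f)
  expect_error(read_fasta(f), "duplicate.*P1")
  writeLines(c(">P1", "ACDE", ">P2", ""), f)
  expect_error(read_fasta(f), "empty sequence.*P2")
})

test_that("long dialect encodes absence as the conditionally negative 0", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tL1", "P2\tL1"), f)
  tab <- read_interactions(f, "long", min_class_size = 2)
  expect_identical(tab$protein_ids, c("P1", "P2"))
  expect_identical(tab$ligand_ids, "L1")
  expect_identical(unname(tab$member[, "L1"]), c(1L, 1L))
})

test_that("classes below min_class_size are dropped; empty result errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\tL1", "P2\tL1"), f)
  expect_error(suppressMessages(read_interactions(f, "long", min_class_size = 5)),
               "no ligand class")
  writeLines(c("P1\tL1", "P2\tL1", "P3\tL2"), f)
  expect_message(tab <- read_interactions(f, "long", min_class_size = 2),
                 "dropping.*L2")
  expect_identical(tab$ligand_ids, "L1")
  # proteins left with no class survive as complement-only examples
  expect_true("P3" %in% tab$protein_ids)
})

test_that("wide and long dialects of one random table are equivalent", {
  set.seed(202)
  for (rep in 1:5) {
    member <- matrix(rbinom(24, 1, 0.5), nrow = 8, ncol = 3,
                     dimnames = list(paste0("P", 1:8), paste0("L", 1:3)))
    # guarantee at least one positive per ligand so both dialects see all ids
    member[cbind(1:3, 1:3)] <- 1L
    fw <- withr::local_tempfile(fileext = ".tsv")
    fl <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(
      data.frame(protein_id = rownames(member), member, check.names = FALSE),
      fw, sep = "\t", quote = FALSE, row.names = FALSE)
    pairs <- which(member == 1L, arr.ind = TRUE)
    writeLines(paste(rownames(member)[pairs[, 1]],
                     colnames(member)[pairs[, 2]], sep = "\t"), fl)
    wide <- read_interactions(fw, "wide", min_class_size = 1)
    long <- read_interactions(fl, "long", min_class_size = 1)
    # long dialect only knows proteins/ligands with a positive pair; align
    expect_identical(wide$member[long$protein_ids, long$ligand_ids],
                     long$member)
  }
})

test_that("class-size filtering is idempotent", {
  member <- matrix(rbinom(40, 1, 0.6), nrow = 10, ncol = 4,
                   dimnames = list(paste0("P", 1:10), paste0("L", 1:4)))
  tab <- suppressMessages(filter_classes(interaction_table(member), 5))
  expect_identical(suppressMessages(filter_classes(tab, 5)), tab)
})

test_that("non-binary cells are rejected in the wide dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tL1", "P1\t2"), f)
  expect_error(read_interactions(f, "wide", 1), "0 or 1")
})

test_that("identity similarity scores equal standard residues 1, all else 0", {
  sim <- load_similarity("identity")
  expect_equal(sim$kind, "identity")
  expect_equal(sim$values["A", "A"], 1)
  expect_equal(sim$values["A", "C"], 0)
  # ambiguity codes carry no evidence, even against themselves
  for (amb in c("X", "B", "Z", "U", "O"))
    expect_equal(sim$values[amb, amb], 0)
})

test_that("NCBI matrix files parse symmetrically and round-trip values", {
  path <- system.file("extdata", "BLOSUM62.txt", package = "posim")
  sim <- load_similarity(path)
  expect_equal(sim$kind, "matrix")
  expect_true(isSymmetric(unname(sim$values)))
  # value read back from the file itself
  raw <- read.table(path, header = TRUE, check.names = FALSE)
  expect_equal(sim$values["W", "W"], raw["W", "W"])
  expect_equal(sim$values["W", "W"], 11)
})

test_that("parsed BLOSUM62 agrees with the Biostrings reference matrix", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  sim <- load_similarity(system.file("extdata", "BLOSUM62.txt",
                                     package = "posim"))
  # ambiguity-code cells (B, Z, X) vary between published copies of the
  # matrix; the 20 standard residues are the meaningful comparison
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(sim$values[std, std], BLOSUM62[std, std] + 0)
})

test_that("incomplete or asymmetric matrix files are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("   A  C", "A  4  0"), f)             # missing row C
  expect_error(load_similarity(f), "incomplete|missing")
  writeLines(c("   A  C", "A  4  1", "C  0  9"), f)  # asymmetric
  expect_error(load_similarity(f), "symmetric")
})
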