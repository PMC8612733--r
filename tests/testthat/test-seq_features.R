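test_that("protein sequences are restricted to canonical residues", {
  expect_error(protein_sequence("x", ""), "empty")
  expect_error(protein_sequence("x", "ABZ"), "non-canonical")
  s <- protein_sequence("x", "acdef")
  expect_identical(s$residues, "ACDEF")
  expect_identical(length(s), 5L)
})

test_that("NCPR profiles match hand counts and report window centers", {
  expect_equal(ncpr_profile(protein_sequence("g", "GGGGG"))$ncpr, 0)
  expect_equal(ncpr_profile(protein_sequence("k", "KKKKK"))$ncpr, 1)
  expect_equal(ncpr_profile(protein_sequence("m", "RKDDE"))$ncpr, -0.2)
  p <- ncpr_profile(protein_sequence("x", "GGRKDDEGG"))
  expect_identical(p$center, 3:7)            # window start i reported at i+2
  expect_identical(nrow(p), 9L - 5L + 1L)
  expect_error(ncpr_profile(protein_sequence("x", "GGG")), "shorter")
  expect_error(ncpr_profile(protein_sequence("x", "GGGGGG"), window = 4),
               "odd")
})

test_that("NCPR reconciles with a brute-force per-residue charge sum", {
  charge1 <- function(ch) (ch %in% c("R", "K")) - (ch %in% c("D", "E"))
  withr::with_seed(5, {
    for (rep in 1:10) {
      L <- sample(12:60, 1)
      chars <- sample(c("A", "G", "R", "K", "D", "E", "H", "Y", "S"), L,
                      replace = TRUE)
      s <- protein_sequence("r", paste(chars, collapse = ""))
      p <- ncpr_profile(s, 5)
      expect_true(all(p$ncpr >= -1 & p$ncpr <= 1))
      # sum over windows of (window value x window size) counts each residue
      # once per window covering it
      coverage <- vapply(seq_len(L), function(i) {
        sum(seq_len(L - 5 + 1) <= i & seq_len(L - 5 + 1) >= i - 4)
      }, 0)
      expect_equal(sum(p$ncpr * 5),
                   sum(charge1(chars) * coverage))
      # histidine carries no charge
      expect_equal(ncpr_profile(protein_sequence("h", "HHHHH"))$ncpr, 0)
    }
  })
})

test_that("residue-class composition counts the mutagenesis classes", {
  s <- protein_sequence("x", "YYRKD")
  comp <- residue_class_composition(s)
  counts <- setNames(comp$count, comp$class)
  expect_identical(counts[["Y"]], 2L)
  expect_identical(counts[["RK"]], 2L)
  expect_identical(counts[["DE"]], 1L)
  expect_identical(counts[["QN"]], 0L)
  expect_identical(counts[["VMF"]], 0L)
  expect_error(residue_class_composition(s, c(3, 9)), "invalid region")
  # additivity over a disjoint cover
  long <- protein_sequence("y", "YYRKDQQNVMFAAGG")
  a <- residue_class_composition(long, c(1, 7))
  b <- residue_class_composition(long, c(8, 15))
  whole <- residue_class_composition(long)
  expect_equal(a$count + b$count, whole$count)
})

test_that("substitution rules rewrite exactly the mapped residues in the region", {
  s <- protein_sequence("x", "AYRYK")
  r1 <- substitution_rule("Y to S", c(1, 5), c(Y = "S"))
  expect_identical(apply_substitution_rule(s, r1)$residues, "ASRSK")
  r2 <- substitution_rule("RK to G", c(1, 5), c(R = "G", K = "G"))
  expect_identical(apply_substitution_rule(s, r2)$residues, "AYGYG")
  # empty mapping is the identity; id still records the rule
  r0 <- substitution_rule("noop", c(1, 5), character(0))
  expect_identical(apply_substitution_rule(s, r0)$residues, s$residues)
  # region restriction
  r3 <- substitution_rule("late Y to S", c(3, 5), c(Y = "S"))
  expect_identical(apply_substitution_rule(s, r3)$residues, "AYRSK")
  # idempotent when replacements are not themselves keys
  once <- apply_substitution_rule(s, r1)
  twice <- apply_substitution_rule(once, r1)
  expect_identical(twice$residues, once$residues)
  expect_identical(nchar(once$residues), nchar(s$residues))
  expect_error(substitution_rule("bad", c(1, 5), c(Y = "X?")), "canonical")
})

test_that("deletion variants remove exactly the interval", {
  withr::with_seed(2, {
    chars <- sample(c("A", "G", "Y", "R", "K", "D", "E", "P", "Q", "N"),
                    324, replace = TRUE)
  })
  s <- protein_sequence("full", paste(chars, collapse = ""))
  d <- deletion_variant(s, c(1, 127))
  expect_identical(length(d), 324L - 127L)
  expect_identical(substr(d$residues, 1, 10), paste(chars[128:137], collapse = ""))
  expect_error(deletion_variant(s, c(1, 324)), "whole sequence")
  expect_error(deletion_variant(s, c(0, 5)), "invalid")
  # composability: deleting 1-55 then the mapped remainder of 56-127
  d1 <- deletion_variant(s, c(1, 55))
  d2 <- deletion_variant(d1, c(1, 72))      # 56-127 in original coordinates
  expect_identical(d2$residues, d$residues)
})

test_that("the canonical CTD rules strip their residue classes from the region", {
  withr::with_seed(3, {
    chars <- sample(c("A", "G", "Y", "R", "K", "D", "E", "P", "Q", "N", "S",
                      "V", "M", "F"), 324, replace = TRUE)
  })
  s <- protein_sequence("wt", paste(chars, collapse = ""))
  rules <- ctd_substitution_rules()
  ys <- apply_substitution_rule(s, rules[["Y to S"]])
  ctd <- substr(ys$residues, 128, 324)
  expect_false(grepl("Y", ctd))
  expect_identical(substr(ys$residues, 1, 127), substr(s$residues, 1, 127))
  rkg <- apply_substitution_rule(s, rules[["RK to G"]])
  expect_false(grepl("[RK]", substr(rkg$residues, 128, 324)))
  # class counts after substitution: basic residues gone from the region
  comp <- residue_class_composition(rkg, c(128, 324))
  expect_identical(comp$count[comp$class == "RK"], 0L)
})

test_that("FASTA round-trips sequences through Biostrings", {
  s1 <- protein_sequence("seq1", "MKTAYIAKQR")
  s2 <- protein_sequence("seq2", "GGSSYYRRKK")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(s1, s2), path)
  back <- read_fasta(path)
  expect_identical(names(back), c("seq1", "seq2"))
  expect_identical(back$seq1$residues, s1$residues)
  expect_identical(back$seq2$residues, s2$residues)
})
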