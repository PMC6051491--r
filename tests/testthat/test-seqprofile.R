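test_that("charge composition counts D+E and R+K with His excluded", {
  cc <- charge_composition("DDEERRKK")
  expect_equal(cc$pct_acidic, 50)
  expect_equal(cc$pct_basic, 50)
  expect_equal(cc$ratio_neg_pos, 1.0)
  cc2 <- charge_composition("DDDRK")
  expect_equal(cc2$pct_acidic, 60)
  expect_equal(cc2$pct_basic, 40)
  expect_equal(cc2$ratio_neg_pos, 1.5)
  g <- suppressMessages(charge_composition("GGGG"))
  expect_equal(g$pct_acidic, 0)
  expect_true(is.na(g$ratio_neg_pos))
  h <- charge_composition("DDHH")  # His is not basic here
  expect_equal(h$n_basic, 0L, ignore_attr = TRUE)
})

test_that("percentages are case-invariant and X is excluded from denominators", {
  up <- charge_composition("DEKRAG")
  lo <- charge_composition("dekrag")
  expect_equal(lo$pct_acidic, up$pct_acidic)
  withx <- charge_composition("DEXXKR")
  expect_identical(withx$n_total, 4L)
  expect_equal(withx$pct_acidic, 50)
})

test_that("domain profiles match planted substrings and sum to the global counts", {
  seq <- "DDDDKKRR"
  doms <- data.frame(name = c("left", "right"), start = c(1, 5), end = c(4, 8))
  prof <- domain_charge_profiles(seq, doms)
  expect_true(is.na(prof$left$ratio_neg_pos))   # 4 acidic, 0 basic
  expect_equal(prof$right$ratio_neg_pos, 0)     # 0 acidic, 4 basic
  whole <- domain_charge_profiles(seq, data.frame(name = "all", start = 1, end = 8))
  expect_equal(whole$all, charge_composition(seq))
  expect_error(domain_charge_profiles(seq, data.frame(name = "bad", start = 1, end = 9)),
               "outside")
  expect_error(domain_charge_profiles(seq,
    data.frame(name = c("a", "b"), start = c(1, 3), end = c(4, 8))), "overlap")
  # domain tiling: per-domain counts sum to whole-sequence counts
  sim <- simulate_sequence(sequence_sim_params(length = 500, seed = 6))
  doms2 <- data.frame(name = c("n", "exo", "palm", "fingers", "thumb"),
                      start = c(1, 101, 221, 331, 401),
                      end = c(100, 220, 330, 400, 500))
  pr <- domain_charge_profiles(sim$record, doms2)
  expect_identical(sum(vapply(pr, `[[`, 0L, "n_acidic")),
                   charge_composition(sim$record)$n_acidic)
  expect_identical(sum(vapply(pr, `[[`, 0L, "n_basic")),
                   charge_composition(sim$record)$n_basic)
})

test_that("hydrophobic classes split bulky (FIL) from small (GAST) side chains", {
  expect_equal(hydrophobic_classes("FILFIL")$pct_bulky, 100)
  expect_equal(hydrophobic_classes("FILFIL")$pct_small, 0)
  expect_equal(hydrophobic_classes("GAST")$pct_small, 100)
  h <- hydrophobic_classes("FGDR")
  expect_equal(h$pct_bulky, 25)
  expect_equal(h$pct_small, 25)
})

test_that("unique acidic positions require acidity in query but not subject", {
  u <- unique_acidic_positions(aligned_pair("DAKE", "DAKQ"))
  expect_identical(u$position, 4L)
  expect_identical(u$residue, "E")
  expect_identical(nrow(unique_acidic_positions(aligned_pair("DEAK", "DEAK"))), 0L)
  gaps <- unique_acidic_positions(aligned_pair("ED--", "--AA"))
  expect_identical(gaps$position, c(1L, 2L))
  nogap <- unique_acidic_positions(aligned_pair("ED--", "--AA"),
                                   gap_is_unique = FALSE)
  expect_identical(nrow(nogap), 0L)
  # a position acidic in both sequences is never reported
  both <- unique_acidic_positions(aligned_pair("DE", "ED"))
  expect_identical(nrow(both), 0L)
  expect_error(aligned_pair("ABC", "AB"), "equal length")
  expect_error(unique_acidic_positions(aligned_pair("DAKE", "DAKQ"),
                                       query = "DAKK"),
               "inconsistent")
})

test_that("disorder overlap reports percentages by tag and NA for empty sets", {
  ov <- disorder_overlap(3L, c(0.1, 0.2, 0.9))
  expect_equal(ov$overall_pct, 100)
  empty <- disorder_overlap(data.frame(position = integer(),
                                       residue = character()),
                            runif(10))
  expect_true(is.na(empty$overall_pct))
  expect_identical(empty$n_positions, 0L)
  expect_error(disorder_overlap(5L, c(0.1, 0.2)), "beyond")
  expect_error(disorder_overlap(1L, c(0.3, 1.4)), "\\[0, 1\\]")
})

test_that("sequence generator plants composition, enrichment and disorder layout", {
  p <- sequence_sim_params(length = 100, target_acidic_fraction = 0.2,
                           target_basic_fraction = 0.1,
                           disorder_segments = list(c(11, 40)),
                           acidic_enrichment_in_disorder = 1.0, seed = 2)
  sim <- simulate_sequence(p)
  cc <- charge_composition(sim$record)
  expect_equal(cc$pct_acidic, 20)
  expect_equal(cc$pct_basic, 10)
  pos <- data.frame(position = c(sim$truth$asp_positions, sim$truth$glu_positions),
                    residue = rep(c("D", "E"), c(length(sim$truth$asp_positions),
                                                 length(sim$truth$glu_positions))))
  ov <- disorder_overlap(pos, sim$disorder)
  expect_equal(ov$overall_pct, 100)
  expect_true(all(sim$disorder[11:40] >= 0.5))
  expect_true(all(sim$disorder[-(11:40)] < 0.5))
  # planted Asp enrichment at the 63% level on a long sequence
  p2 <- sequence_sim_params(length = 800, target_acidic_fraction = 0.18,
                            target_basic_fraction = 0.08,
                            disorder_segments = list(c(50, 150), c(300, 420),
                                                     c(600, 700)),
                            acidic_enrichment_in_disorder = 0.63, seed = 7)
  sim2 <- simulate_sequence(p2)
  asp <- data.frame(position = sim2$truth$asp_positions, residue = "D")
  ov2 <- disorder_overlap(asp, sim2$disorder)
  expect_lt(abs(ov2$overall_pct - 63), 5)
  expect_error(sequence_sim_params(length = 100, target_acidic_fraction = 0.7,
                                   target_basic_fraction = 0.5),
               "infeasible")
  expect_identical(simulate_sequence(p2)$record, sim2$record)  # reproducible
})
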