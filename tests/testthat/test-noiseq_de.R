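de_expr <- function(tpm) {
  make_expr(tpm, species = rep("sp1", ncol(tpm)),
            stage = rep(c("A", "B"), each = ncol(tpm) / 2),
            replicate = rep(1:(ncol(tpm) / 2), 2))
}

de_contrast <- function(tpm) {
  tag_contrast(colnames(tpm)[seq_len(ncol(tpm) / 2)],
               colnames(tpm)[-seq_len(ncol(tpm) / 2)], "A vs B")
}

test_that("signal statistics implement M and D on condition means", {
  tpm <- matrix(c(10, 40, 0,   10, 40, 0,    # condition A replicates
                  10, 10, 2,   10, 10, 2),   # condition B replicates
                3, 4, dimnames = list(paste0("g", 1:3),
                                      c("A1", "A2", "B1", "B2")))
  sig <- signal_statistics(de_expr(tpm), de_contrast(tpm), pseudo = 0.5)
  expect_equal(sig["g1", c("M", "D")],
               data.frame(M = 0, D = 0, row.names = "g1"))
  expect_equal(sig["g2", "M"], 2)
  expect_equal(sig["g2", "D"], 30)
  # zero mean smoothed by pseudo only inside the ratio; D uses raw means
  expect_equal(sig["g3", "M"], log2(0.5 / 2))
  expect_equal(sig["g3", "D"], 2)
  # absent libraries are a validation error
  expect_error(signal_statistics(de_expr(tpm),
                                 tag_contrast("A1", "nope")), "absent")
})

test_that("signal statistics agree with direct recomputation on random input", {
  set.seed(51)
  tpm <- matrix(rlnorm(200, 2, 1), 50, 4,
                dimnames = list(paste0("g", 1:50),
                                c("A1", "A2", "B1", "B2")))
  sig <- signal_statistics(de_expr(tpm), de_contrast(tpm))
  m1 <- (tpm[, 1] + tpm[, 2]) / 2
  m2 <- (tpm[, 3] + tpm[, 4]) / 2
  expect_equal(sig$M, unname(log2(m1 / m2)))
  expect_equal(sig$D, unname(abs(m1 - m2)))
})

test_that("noise distribution pools within-condition replicate pairs", {
  tpm <- matrix(c(1, 2, 3, 1, 2, 3, 5, 6, 7, 5, 6, 7), 3, 4,
                dimnames = list(paste0("g", 1:3),
                                c("A1", "A2", "B1", "B2")))
  # identical replicates -> all noise pairs are (0, 0)
  noise <- noise_distribution(de_expr(tpm), de_contrast(tpm))
  expect_equal(nrow(noise), 6L)  # 3 genes x (1 pair per condition x 2)
  expect_true(all(noise == 0))
  # r < 2 errors naming the condition
  expect_error(noise_distribution(de_expr(tpm),
                                  tag_contrast("A1", c("B1", "B2"))),
               "condition_1")
})

test_that("noise set equals exhaustive enumeration on a toy matrix", {
  set.seed(52)
  tpm <- matrix(rlnorm(30, 2, 1), 5, 6,
                dimnames = list(paste0("g", 1:5),
                                c("A1", "A2", "A3", "B1", "B2", "B3")))
  ct <- tag_contrast(c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expr <- make_expr(tpm, rep("sp1", 6), rep(c("A", "B"), each = 3),
                    rep(1:3, 2))
  noise <- noise_distribution(expr, ct, pseudo = 0.5)
  # 5 genes x 3 pairs per condition x 2 conditions
  expect_equal(nrow(noise), 30L)
  manual <- NULL
  for (cols in list(c("A1", "A2", "A3"), c("B1", "B2", "B3"))) {
    for (pair in list(1:2, c(1, 3), 2:3)) {
      x <- tpm[, cols[pair[1]]]; y <- tpm[, cols[pair[2]]]
      manual <- rbind(manual, cbind(abs(log2(x / y)), abs(x - y)))
    }
  }
  expect_equal(sort(noise[, "absM"]), sort(manual[, 1]))
  expect_equal(sort(noise[, "absD"]), sort(manual[, 2]))
})

test_that("P1 counts strict joint exceedance over the noise set", {
  noise <- cbind(absM = c(0.1, 0.5, 1.0), absD = c(1, 5, 10))
  sig <- data.frame(M = c(2, 0, 0.7, 0.5), D = c(20, 0, 7, 5))
  p1 <- de_probability(sig, noise)
  expect_equal(p1[1], 1)      # dominates every noise pair
  expect_equal(p1[2], 0)      # (0,0): strict inequality
  expect_equal(p1[3], 2 / 3)
  expect_equal(p1[4], 1 / 3)  # ties at (0.5, 5) do not count
  expect_error(de_probability(sig, noise[0, , drop = FALSE]), "noise")
})

test_that("P1 equals the brute-force double loop on synthetic instances", {
  set.seed(53)
  for (i in 1:3) {
    tpm <- matrix(rlnorm(80, 2, 1.5), 20, 4,
                  dimnames = list(paste0("g", 1:20),
                                  c("A1", "A2", "B1", "B2")))
    tpm[sample(length(tpm), 8)] <- 0
    expr <- de_expr(tpm)
    ct <- de_contrast(tpm)
    sig <- signal_statistics(expr, ct)
    noise <- noise_distribution(expr, ct)
    expect_equal(de_probability(sig, noise),
                 oracle_p1(abs(sig$M), sig$D, noise))
  }
})

test_that("P1 is monotone in |M| and |D| against a fixed noise set", {
  set.seed(54)
  noise <- cbind(absM = runif(50, 0, 2), absD = runif(50, 0, 20))
  base <- data.frame(M = 0.8, D = 6)
  p_base <- de_probability(base, noise)
  for (i in 1:20) {
    stronger <- data.frame(M = base$M + runif(1), D = base$D + runif(1, 0, 5))
    expect_gte(de_probability(stronger, noise), p_base)
  }
})

test_that("swapping condition labels negates M and preserves D and P1", {
  set.seed(55)
  tpm <- matrix(rlnorm(120, 2, 1.5), 30, 4,
                dimnames = list(paste0("g", 1:30),
                                c("A1", "A2", "B1", "B2")))
  expr <- de_expr(tpm)
  fwd <- tag_de(expr, tag_contrast(c("A1", "A2"), c("B1", "B2")))
  rev <- tag_de(expr, tag_contrast(c("B1", "B2"), c("A1", "A2")))
  expect_equal(rev$M, -fwd$M)
  expect_equal(rev$D, fwd$D)
  expect_equal(rev$P1, fwd$P1)
  # permuting gene order permutes outputs identically
  perm <- sample(30)
  expr_p <- de_expr(tpm[perm, ])
  fwd_p <- tag_de(expr_p, tag_contrast(c("A1", "A2"), c("B1", "B2")))
  expect_equal(fwd_p$P1, fwd$P1[perm])
})

test_that("the calling rule gates on both probability and fold change", {
  fit <- structure(data.frame(gene = c("a", "b", "c"),
                              M = c(0.5, -1.2, 2),
                              P1 = c(0.85, 0.8, 0.79)),
                   class = c("tag_de", "data.frame"),
                   contrast = tag_contrast("x", "y", "toy"))
  called <- call_degs(fit)
  expect_equal(called$significant, c(FALSE, TRUE, FALSE))
  expect_equal(called$direction[2], "up_condition_2")
  # flagged genes at the default threshold carry odds of at least 4:1
  expect_equal(threshold_odds(0.8), 4)
  p1 <- called$P1[called$significant]
  expect_true(all(p1 / (1 - p1) >= 4))
})

test_that("deg_counts and summary tally directions per contrast", {
  set.seed(56)
  tpm <- matrix(rlnorm(80, 2, 0.1), 20, 4,
                dimnames = list(paste0("g", 1:20),
                                c("A1", "A2", "B1", "B2")))
  tpm[1, 1:2] <- tpm[1, 1:2] * 50   # strong up in condition 1
  tpm[2, 3:4] <- tpm[2, 3:4] * 50   # strong up in condition 2
  fit <- tag_de(de_expr(tpm), de_contrast(tpm))
  counts <- deg_counts(fit)
  expect_equal(counts$up_condition_1, 1L)
  expect_equal(counts$up_condition_2, 1L)
  expect_equal(counts$significant,
               counts$up_condition_1 + counts$up_condition_2)
  s <- summary(fit)
  expect_equal(s$counts, counts)
})
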