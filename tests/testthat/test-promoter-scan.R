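# PWM parsing, scoring, scanning, element counting.

pwms <- example_pwms()

test_that("JASPAR parsing captures id, name and matrix shape", {
  p <- pwms$ebox
  expect_identical(p$id, "EBOX_SYN")
  expect_match(p$name, "stand-in")
  expect_identical(dim(p$counts), c(4L, 10L))
  expect_identical(rownames(p$counts), c("A", "C", "G", "T"))
  # bare four-row block without labels parses too
  tmp <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0000.0 TEST", "1 2 3 9", "9 1 1 1", "0 8 0 5",
               "2 1 8 1"), tmp)
  q <- read_pfm(tmp)
  expect_identical(q$id, "MA0000.0")
  expect_identical(q$name, "TEST")
  expect_identical(q$length, 4L)
  # unequal column sums across positions are accepted (raw counts)
  expect_true(length(unique(colSums(q$counts))) > 1)
  # malformed rows are rejected with a location
  writeLines(c(">B bad", "1 2 3", "1 2 3 4", "1 2 3 4", "1 2 3 4"), tmp)
  expect_error(read_pfm(tmp), "unequal length|malformed")
})

test_that("relative score spans [0, 1] with consensus at 1", {
  for (p in pwms) {
    expect_equal(relative_score(p, p$consensus), 1)
    anti <- paste(c("A", "C", "G", "T")[apply(p$lods, 2, which.min)],
                  collapse = "")
    expect_equal(relative_score(p, anti), 0)
  }
  expect_error(relative_score(pwms$ebox, "ACGT"), "length")
})

test_that("strand symmetry: minus strand scores the reverse complement", {
  set.seed(5)
  p <- pwms$rre
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), p$length, replace = TRUE),
               collapse = "")
    expect_equal(relative_score(p, s, "+"),
                 relative_score(p, clockdde:::revcomp(s), "-"))
  }
})

test_that("planted consensus motifs are located on the right strand", {
  set.seed(11)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  p <- pwms$ebox
  seq <- paste0(substr(bg, 1, 137), p$consensus,
                substr(bg, 138 + p$length, 1000))
  hits <- pwm_scan(promoter_region("g", substr(seq, 1, 1000)), p,
                   threshold = 0.95)
  expect_true(any(hits$start == 138 & hits$strand == "+"))
  # planted reverse complement found on the minus strand
  seq2 <- paste0(substr(bg, 1, 400), clockdde:::revcomp(p$consensus),
                 substr(bg, 401 + p$length, 1000))
  hits2 <- pwm_scan(promoter_region("g", substr(seq2, 1, 1000)), p,
                    threshold = 0.95)
  expect_true(any(hits2$start == 401 & hits2$strand == "-"))
})

test_that("scan equals the exhaustive brute-force oracle", {
  set.seed(21)
  for (rep in 1:6) {
    plan <- data.frame(gene = "g", k_ebox = sample(0:3, 1),
                       k_rre = sample(0:2, 1), k_dbox = sample(0:2, 1))
    prom <- generate_promoters(plan, length = 4000, seed = 100 + rep)
    seq <- prom$sequences[[1]]
    for (cls in c("ebox", "rre", "dbox")) {
      n_scan <- nrow(pwm_scan(promoter_region("g", seq), pwms[[cls]]))
      n_oracle <- brute_force_scan_count(seq, pwms[[cls]])
      expect_identical(n_scan, n_oracle)
    }
  }
})

test_that("windows containing N are skipped, not scored", {
  p <- pwms$dbox
  seq <- paste0("ACGTACGTAC", p$consensus, "NACGTACGTA")
  hits <- pwm_scan(promoter_region("g", seq), p, threshold = 0.9)
  expect_true(all(hits$start == 11))
  # every surviving window is N-free even at threshold 0
  seqN <- paste0("ACGTACGTAC", sub("T", "N", p$consensus), "AACGTACGTA")
  h <- pwm_scan(promoter_region("g", seqN), p, threshold = 0)
  for (i in seq_len(nrow(h)))
    expect_false(grepl("N", substr(seqN, h$start[i], h$end[i])))
})

test_that("threshold monotonicity: higher threshold never adds hits", {
  prom <- generate_promoters(
    data.frame(gene = "g", k_ebox = 2, k_rre = 1, k_dbox = 1),
    length = 5000, seed = 9)
  reg <- promoter_region("g", prom$sequences[[1]])
  for (p in pwms) {
    counts <- vapply(c(0.7, 0.8, 0.85, 0.9, 0.99),
                     function(th) nrow(pwm_scan(reg, p, threshold = th)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("scanning the reverse complement preserves totals, swaps strands", {
  prom <- generate_promoters(
    data.frame(gene = "g", k_ebox = 1, k_rre = 1, k_dbox = 0),
    length = 3000, seed = 13)
  seq <- prom$sequences[[1]]
  for (p in pwms[c("ebox", "rre")]) {
    h_fwd <- pwm_scan(promoter_region("g", seq), p)
    h_rev <- pwm_scan(promoter_region("g", clockdde:::revcomp(seq)), p)
    expect_identical(nrow(h_fwd), nrow(h_rev))
    expect_identical(sum(h_fwd$strand == "+"), sum(h_rev$strand == "-"))
  }
})

test_that("count_elements returns counts with provenance, deterministically", {
  prom <- generate_promoters(
    data.frame(gene = "g", k_ebox = 2, k_rre = 1, k_dbox = 0),
    length = 5000, seed = 4)
  reg <- promoter_region("g", prom$sequences[[1]])
  ec1 <- count_elements(reg, pwms$ebox, pwms$rre, pwms$dbox)
  ec2 <- count_elements(reg, pwms$ebox, pwms$rre, pwms$dbox)
  expect_identical(ec1[c("n1", "n2", "n3")], ec2[c("n1", "n2", "n3")])
  expect_gte(ec1$n1, 2)  # plantings recovered; background may add
  expect_gte(ec1$n2, 1)
  expect_identical(nrow(ec1$hits), ec1$n1 + ec1$n2 + ec1$n3)
  # a stringent threshold on an empty plan yields (0, 0, 0)
  empty <- generate_promoters(
    data.frame(gene = "e", k_ebox = 0, k_rre = 0, k_dbox = 0),
    length = 2000, seed = 5)
  ec0 <- count_elements(promoter_region("e", empty$sequences[[1]]),
                        pwms$ebox, pwms$rre, pwms$dbox, threshold = 0.999)
  expect_identical(c(ec0$n1, ec0$n2, ec0$n3), c(0L, 0L, 0L))
})

test_that("regions shorter than the motif warn and return no hits", {
  expect_warning(h <- pwm_scan(promoter_region("g", "ACGT"), pwms$ebox),
                 "shorter")
  expect_identical(nrow(h), 0L)
})

test_that("BED export is 0-based half-open", {
  prom <- generate_promoters(
    data.frame(gene = "g", k_ebox = 1, k_rre = 0, k_dbox = 0),
    length = 2000, seed = 2)
  hits <- pwm_scan(promoter_region("g", prom$sequences[[1]]), pwms$ebox)
  tmp <- tempfile(fileext = ".bed")
  write_hits_bed(hits, tmp)
  bed <- read.table(tmp, sep = "\t")
  expect_equal(bed$V2, hits$start - 1L)
  expect_equal(bed$V3, hits$end)
  expect_true(all(bed$V3 - bed$V2 == pwms$ebox$length))
})
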