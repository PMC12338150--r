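test_that("hit filtering applies the inclusive E-value rule and best-hit dedup", {
  hits <- data.frame(
    query_id = c("BaiB", "BaiB", "BaiE", "BaiE", "BaiG"),
    cds_id = c("c1", "c1", "c2", "c3", "c4"),
    evalue = c(1e-20, 1e-15, 1e-9, 1e-10, 1e-12),
    bit_score = c(200, 180, 50, 60, 90))
  out <- filter_hits(hits)
  expect_false(any(out$evalue > 1e-10))
  expect_true(1e-10 %in% out$evalue)            # boundary is inclusive
  b <- out[out$query_id == "BaiB", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$evalue, 1e-20)                 # best hit kept
  expect_false("c2" %in% out$cds_id)            # 1e-9 removed
})

test_that("operon detection handles canonical, partial and dispersed cases", {
  mk_cds <- function(ids, starts, ends, contig = "ctg1")
    data.frame(cds_id = ids, contig_id = contig, start = starts, end = ends,
               strand = "+")
  mk_hits <- function(genes, ids)
    data.frame(query_id = genes, cds_id = ids, evalue = 1e-30,
               bit_score = 300)
  # 8 genes in 20 kb: canonical
  cds8 <- mk_cds(paste0("c", 1:8), seq(1000, 19000, length.out = 8),
                 seq(2200, 20200, length.out = 8))
  call8 <- detect_bai_operon(mk_hits(BAI_GENES, paste0("c", 1:8)), cds8)
  expect_equal(call8$n_genes, 8)
  expect_true(call8$canonical)
  expect_lt(call8$span_bp, 1e5)
  # 7 genes (no BaiI) in 15 kb: still canonical
  cds7 <- mk_cds(paste0("c", 1:7), seq(1000, 14000, length.out = 7),
                 seq(2100, 15100, length.out = 7))
  call7 <- detect_bai_operon(mk_hits(BAI_CANONICAL, paste0("c", 1:7)), cds7)
  expect_true(call7$canonical)
  expect_setequal(call7$genes_present, BAI_CANONICAL)
  # 8 genes over 150 kb: not canonical, densest sub-window reported
  cds_wide <- mk_cds(paste0("c", 1:8), seq(1000, 150000, length.out = 8),
                     seq(2000, 151000, length.out = 8))
  call_wide <- detect_bai_operon(mk_hits(BAI_GENES, paste0("c", 1:8)),
                                 cds_wide)
  expect_false(call_wide$canonical)
  expect_lt(call_wide$n_genes, 8)
  # genes split across contigs cannot share a window
  cds_split <- rbind(mk_cds(paste0("c", 1:4), 1:4 * 2000, 1:4 * 2000 + 900),
                     mk_cds(paste0("c", 5:8), 1:4 * 2000, 1:4 * 2000 + 900,
                            contig = "ctg2"))
  call_split <- detect_bai_operon(mk_hits(BAI_GENES, paste0("c", 1:8)),
                                  cds_split)
  expect_false(call_split$canonical)
  expect_equal(call_split$n_genes, 4)
  # hits on unknown CDS are excluded with a warning
  expect_warning(
    orphan <- detect_bai_operon(mk_hits(c("BaiB", "BaiE"), c("c1", "zz")),
                                cds8),
    "absent")
  expect_equal(orphan$genes_present, "BaiB")
  # single gene: span = end - start
  single <- detect_bai_operon(mk_hits("BaiB", "c1"), cds8)
  expect_equal(single$span_bp, cds8$end[1] - cds8$start[1])
})

test_that("operon detector agrees with brute-force subset search", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    contigs <- sample(c("ctg1", "ctg2"), n, replace = TRUE,
                      prob = c(0.8, 0.2))
    starts <- sample.int(2e5, n)
    cds <- data.frame(cds_id = paste0("c", 1:n), contig_id = contigs,
                      start = starts, end = starts + sample(500:2500, n,
                                                            replace = TRUE),
                      strand = "+")
    hits <- data.frame(query_id = sample(BAI_GENES, n, replace = TRUE),
                       cds_id = cds$cds_id, evalue = 1e-30,
                       bit_score = runif(n, 100, 500))
    got <- detect_bai_operon(hits, cds)
    want <- oracle_operon(hits, cds, 1e5)
    expect_equal(got$n_genes, want$n_genes, info = paste("instance", i))
    if (got$n_genes > 0)
      expect_lte(got$span_bp, want$span + 1e-9)
  }
})

test_that("F measure follows the harmonic-mean formula with the TP=0 rule", {
  expect_equal(f_measure(6, 0, 0)$f, 1)
  expect_equal(f_measure(1, 0, 1)$f, 2 / 3)  # recall .5, precision 1
  expect_equal(f_measure(0, 5, 3)$f, 0)
  expect_equal(f_measure(0, 0, 0)$f, 0)
  fm <- f_measure(3, 1, 2)
  expect_equal(fm$recall, 0.6)
  expect_equal(fm$precision, 0.75)
  expect_equal(fm$f, 2 / (1 / 0.6 + 1 / 0.75))
})

test_that("cutoff selection matches the worked examples", {
  r1 <- select_cutoff(c(150, 160), 100)
  expect_equal(r1$cutoff, 150)
  expect_equal(r1$f, 1)
  r2 <- select_cutoff(100, 200)
  expect_equal(r2$cutoff, 100)
  expect_equal(r2$f, 2 / 3)
  r3 <- select_cutoff(50, numeric(0))
  expect_equal(r3$cutoff, 50)
  expect_equal(r3$f, 1)
  expect_error(select_cutoff(numeric(0), 1), "non-empty")
  # the scan covers every candidate with its confusion counts
  expect_equal(nrow(r1$scan), 3)
  expect_equal(r1$scan$tp[r1$scan$threshold == 150], 2)
})

test_that("cutoff selection agrees with the exhaustive scan on random sets", {
  set.seed(41)
  for (i in 1:200) {
    npos <- sample(1:20, 1); nneg <- sample(0:20, 1)
    # integer scores force ties; occasionally all negatives dominate (TP=0
    # at high thresholds)
    pos <- sample(1:30, npos, replace = TRUE)
    neg <- if (nneg) sample(1:40, nneg, replace = TRUE) else numeric(0)
    got <- select_cutoff(pos, neg)
    want <- oracle_cutoff(pos, neg)
    expect_equal(got$f, want$f, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("HSD classification is inclusive at the cutoff and monotone", {
  scores <- data.frame(cds_id = c("a", "b", "c"),
                       class = c("3a", "3a", "7a"),
                       bit_score = c(200, 100, 146.1))
  cut <- c(`3a` = 146.1, `7a` = 220.6, `12a` = 120.2)
  pred <- classify_hsd(scores, cut)
  expect_true(pred$predicted[pred$class == "3a"])   # 200 >= 146.1
  expect_false(pred$predicted[pred$class == "7a"])  # 146.1 < 220.6
  expect_false(pred$predicted[pred$class == "12a"]) # no scores at all
  # boundary score: inclusive
  at <- classify_hsd(data.frame(cds_id = "x", class = "3a",
                                bit_score = 146.1), cut)
  expect_true(at$predicted[at$class == "3a"])
  # support listed in descending score order
  expect_equal(pred$support[pred$class == "3a"], "a")
  # raising cutoffs never adds predictions
  set.seed(8)
  sc <- data.frame(cds_id = paste0("c", 1:30),
                   class = sample(c("3a", "7a", "12a"), 30, replace = TRUE),
                   bit_score = runif(30, 0, 300))
  low <- classify_hsd(sc, c(`3a` = 100, `7a` = 100, `12a` = 100))
  high <- classify_hsd(sc, c(`3a` = 200, `7a` = 200, `12a` = 200))
  expect_true(all(low$predicted | !high$predicted))
})

test_that("PSSM scoring separates members from shuffles and planted families", {
  set.seed(19)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  consensus <- paste(sample(alpha, 60, replace = TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(alpha, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  msa <- vapply(1:6, function(i) mutate(consensus, 5), character(1))
  pssm <- build_pssm(msa)
  member <- msa[1]
  shuffled <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
  expect_gt(score_with_pssm(pssm, member), score_with_pssm(pssm, shuffled))
  # row-order invariance
  expect_equal(score_with_pssm(build_pssm(rev(msa)), member),
               score_with_pssm(pssm, member))
  # planted families are separable with F = 1
  fam_pos <- vapply(1:5, function(i) mutate(consensus, 4), character(1))
  fam_neg <- vapply(1:8, function(i)
    paste(sample(alpha, 60, replace = TRUE), collapse = ""), character(1))
  pos_scores <- vapply(fam_pos, function(s) score_with_pssm(pssm, s),
                       numeric(1))
  neg_scores <- vapply(fam_neg, function(s) score_with_pssm(pssm, s),
                       numeric(1))
  expect_equal(select_cutoff(pos_scores, neg_scores)$f, 1)
  expect_error(build_pssm(c("ACDX", "ACDE")), "X")
  expect_error(score_with_pssm(pssm, "ACDB"), "B")
})

test_that("format readers parse the declared dialects", {
  # BLAST outfmt 6
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("BaiB", "cds_9", "95.2", "300", "12", "1", "1", "300",
                   "1", "300", "2.5e-30", "250.1", sep = "\t"), f)
  hits <- read_blast_tab(f)
  expect_equal(hits$query_id, "BaiB")
  expect_equal(hits$cds_id, "cds_9")
  expect_equal(hits$evalue, 2.5e-30)
  expect_equal(hits$bit_score, 250.1)
  # hmmsearch tblout
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# target name  accession  query name accession  E-value  score  bias",
               "cds_1 - 3a - 1.2e-40 150.3 0.1",
               "cds_2 - 7a - 3.1e-05 18.2 0.0",
               "#"), g)
  tb <- read_hmmer_tblout(g)
  expect_equal(tb$cds_id, c("cds_1", "cds_2"))
  expect_equal(tb$query_id, c("3a", "7a"))
  expect_equal(tb$bit_score, c(150.3, 18.2))
  # GFF3 via a generated proteome
  led <- tiny_panel()
  dir <- withr::local_tempdir()
  pr <- emit_proteomes(led, dir = dir)
  gff <- list.files(dir, pattern = "_genes\\.gff3$", full.names = TRUE)[1]
  cds <- read_gff_cds(gff)
  st <- sub("_genes\\.gff3$", "", basename(gff))
  truth <- pr$cds[pr$cds$strain_id == st, ]
  expect_equal(nrow(cds), nrow(truth))
  expect_setequal(cds$cds_id, truth$cds_id)
  m <- match(truth$cds_id, cds$cds_id)
  expect_equal(cds$start[m], truth$start)
  expect_equal(cds$end[m], truth$end)
})
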