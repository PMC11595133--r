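test_that("pearson_cor: perfect linearity, symmetry, and the t-based p", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), list(r = 1, p = 0))
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), list(r = -1, p = 0))
  # r = 0.8 at n = 5 via an exact integer construction (y = 4x + 3z, z
  # orthogonal to x with equal norm); the oracle evaluates the t CDF itself
  p08 <- r08_pair()
  got <- pearson_cor(p08$x, p08$y)
  expect_equal(got$r, 0.8, tolerance = 1e-14)
  t_oracle <- got$r * sqrt((5 - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(-t_oracle, df = 3), tolerance = 1e-14)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "n >= 3")
})

test_that("pearson_cor matches a sum-based oracle on random vectors", {
  oracle <- function(x, y) {
    n <- length(x)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(t), df = n - 2))
  }
  set.seed(21)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_cor(x, y)
    want <- oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # symmetry and affine invariance (positive slope)
    expect_equal(pearson_cor(y, x)$r, got$r, tolerance = 1e-12)
    expect_equal(pearson_cor(2.5 * x + 1, y)$r, got$r, tolerance = 1e-10)
  }
})

test_that("coexpression edges: sign constraint and strict thresholds", {
  samples <- paste0("s", 1:6)
  a <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("up", samples))
  b <- rbind(up2 = c(2, 4, 6, 8, 10, 12), down = c(6, 5, 4, 3, 2, 1))
  colnames(b) <- samples
  pos <- coexpression_edges(a, b, "x", "positive")
  expect_equal(pos$id_b, "up2")
  expect_equal(pos$r, 1)
  neg <- coexpression_edges(a, b, "x", "negative")
  expect_equal(neg$id_b, "down")
  # self-comparison: every feature correlates perfectly with itself
  self <- coexpression_edges(b, b, "x", "positive")
  expect_true(all(paste(rownames(b), rownames(b)) %in%
                    paste(self$id_a, self$id_b)))
  # sample order mismatch is an error, never silently realigned
  b2 <- b[, c(2, 1, 3:6)]
  expect_error(coexpression_edges(a, b2, "x", "positive"), "mismatch")
})

test_that("r exactly at the threshold is rejected (strict >)", {
  p08 <- r08_pair()
  a <- matrix(p08$x, 1, 5, dimnames = list("x", paste0("s", 1:5)))
  b <- matrix(p08$y, 1, 5, dimnames = list("y", paste0("s", 1:5)))
  r_obs <- stats::cor(p08$x, p08$y)
  at <- coexpression_edges(a, b, "x", "positive", r_threshold = r_obs,
                           p_threshold = 0.99)
  below <- coexpression_edges(a, b, "x", "positive",
                              r_threshold = r_obs - 1e-9, p_threshold = 0.99)
  expect_equal(nrow(at), 0L)
  expect_equal(nrow(below), 1L)
})

fake_feature <- function(id, chrom, start, end, biotype = "mRNA") {
  df <- data.frame(transcript_id = id, gene_id = paste0("g", id),
                   biotype = biotype, chrom = chrom, strand = "+",
                   start = as.integer(start), end = as.integer(end),
                   n_exons = 1L, length = as.integer(end - start + 1),
                   stringsAsFactors = FALSE)
  df$exons <- I(list(cbind(start = as.integer(start), end = as.integer(end))))
  df
}

test_that("cis pairs: overlap, inclusive 100 kb boundary, chromosome gating", {
  genes <- rbind(fake_feature("gA", "chr1", 500000, 501000),
                 fake_feature("gB", "chr1", 800000, 801000),
                 fake_feature("gC", "chr2", 500000, 501000))
  lncs <- rbind(
    fake_feature("l_over", "chr1", 500500, 501500, "lncRNA"),
    fake_feature("l_100k", "chr1", 601000, 602000, "lncRNA"),  # gap 100000
    fake_feature("l_100k1", "chr1", 601001, 602001, "lncRNA"), # gap 100001
    fake_feature("l_chr2", "chr1", 500000, 501000, "lncRNA"))
  edges <- data.frame(
    id_a = c("gA", "gA", "gA", "gC"),
    id_b = c("l_over", "l_100k", "l_100k1", "l_chr2"),
    class_pair = "mRNA-lncRNA", r = 0.95, p = 1e-4,
    required_sign = "positive", stringsAsFactors = FALSE)
  got <- cis_pairs(lncs, genes, edges)
  expect_setequal(got$lncrna_id, c("l_over", "l_100k"))
  expect_equal(got$distance[got$lncrna_id == "l_over"], 0L)
  expect_equal(got$distance[got$lncrna_id == "l_100k"], 100000L)
  # l_chr2's edge partner gC is on another chromosome -> skipped, no error
  expect_false("l_chr2" %in% got$lncrna_id)
  # without a qualifying edge nothing is emitted
  expect_equal(nrow(cis_pairs(lncs, genes, edges[0, ])), 0L)
})

test_that("trans pairs require both a duplex hit and an edge", {
  hits <- data.frame(lncrna_id = c("l1", "l2"), mrna_id = c("m1", "m2"),
                     lnc_start = 1L, lnc_end = 12L, mrna_start = 1L,
                     mrna_end = 12L, stretch_len = 12L,
                     energy = c(-120, -130), stringsAsFactors = FALSE)
  edges <- data.frame(id_a = c("m1", "m3"), id_b = c("l1", "l3"),
                      class_pair = "mRNA-lncRNA", r = 0.9, p = 1e-3,
                      required_sign = "positive", stringsAsFactors = FALSE)
  got <- trans_pairs(hits, edges)
  expect_equal(got$lncrna_id, "l1")   # hit + edge
  expect_false("l2" %in% got$lncrna_id)  # hit without edge
  expect_false("l3" %in% got$lncrna_id)  # edge without hit
})

test_that("miRNA target edges need at least one supporting site", {
  edges <- data.frame(id_a = c("mi1", "mi2"), id_b = c("m1", "m2"),
                      class_pair = "miRNA-mRNA", r = c(-0.9, -0.95),
                      p = 1e-3, required_sign = "negative",
                      stringsAsFactors = FALSE)
  sites <- data.frame(mirna_id = "mi1", target_id = "m1",
                      target_start = 10L, target_end = 31L,
                      align_score = 200, delta_g = -40, seed_perfect = TRUE,
                      stringsAsFactors = FALSE)
  got <- mirna_target_edges(edges, sites)
  expect_equal(got$id_a, "mi1")
  expect_equal(got$align_score, 200)
  expect_equal(nrow(mirna_target_edges(edges, sites[0, ])), 0L)
})

test_that("triplet assembly equals exhaustive enumeration on random graphs", {
  enumerate_oracle <- function(mm, ml, pl) {
    out <- NULL
    for (m in unique(c(mm$id_b, pl$id_a))) for (mi in unique(c(mm$id_a)))
      for (l in unique(c(ml$id_b, pl$id_b))) {
        e1 <- which(mm$id_a == mi & mm$id_b == m)
        e2 <- which(ml$id_a == mi & ml$id_b == l)
        e3 <- which(pl$id_a == m & pl$id_b == l)
        if (length(e1) && length(e2) && length(e3))
          out <- rbind(out, data.frame(mrna_id = m, mirna_id = mi,
                                       lncrna_id = l,
                                       score = pl$r[e3[1]],
                                       stringsAsFactors = FALSE))
      }
    out
  }
  rand_edges <- function(n, ids_a, ids_b, sign) {
    pairs <- expand.grid(id_a = ids_a, id_b = ids_b,
                         stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), n), ]
    pairs$class_pair <- "x"
    pairs$r <- sign * runif(n, 0.81, 0.99)
    pairs$p <- 1e-4
    pairs$required_sign <- if (sign > 0) "positive" else "negative"
    pairs
  }
  set.seed(23)
  for (rep in 1:5) {
    mis <- sprintf("mi%02d", 1:8)
    ms <- sprintf("m%02d", 1:12)
    ls <- sprintf("l%02d", 1:10)
    mm <- rand_edges(25, mis, ms, -1)
    ml <- rand_edges(20, mis, ls, -1)
    pl <- rand_edges(40, ms, ls, +1)
    got <- assemble_triplets(mm, ml, pl)
    want <- enumerate_oracle(mm, ml, pl)
    key <- function(d) sort(paste(d$mrna_id, d$mirna_id, d$lncrna_id))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(key(got), key(want))
      expect_equal(got$cerna_score, got$r_mrna_lncrna)
      expect_false(is.unsorted(rev(got$cerna_score)))
    }
  }
})

test_that("a toy graph gives exactly one triplet, lost without the lnc site", {
  mm_expr <- data.frame(id_a = "mi1", id_b = "m1", class_pair = "miRNA-mRNA",
                        r = -0.9, p = 1e-3, required_sign = "negative",
                        stringsAsFactors = FALSE)
  ml_expr <- data.frame(id_a = "mi1", id_b = "l1",
                        class_pair = "miRNA-lncRNA", r = -0.85, p = 1e-3,
                        required_sign = "negative", stringsAsFactors = FALSE)
  pl <- data.frame(id_a = "m1", id_b = "l1", class_pair = "mRNA-lncRNA",
                   r = 0.93, p = 1e-3, required_sign = "positive",
                   stringsAsFactors = FALSE)
  site <- function(mi, tg) data.frame(
    mirna_id = mi, target_id = tg, target_start = 1L, target_end = 22L,
    align_score = 215, delta_g = -40, seed_perfect = TRUE,
    stringsAsFactors = FALSE)
  mm <- mirna_target_edges(mm_expr, site("mi1", "m1"))
  ml <- mirna_target_edges(ml_expr, site("mi1", "l1"))
  got <- assemble_triplets(mm, ml, pl)
  expect_equal(nrow(got), 1L)
  expect_equal(got$cerna_score, 0.93)
  # drop the lncRNA site: the miRNA-lncRNA edge loses support, no triplet
  ml_none <- mirna_target_edges(ml_expr, site("mi1", "m1"))
  expect_equal(nrow(assemble_triplets(mm, ml_none, pl)), 0L)
})
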