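test_that("individual selection is boundary-inclusive", {
  p <- matrix(c(0.39, 0.40, 0.41, 0.61, 0.60, 0.59), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("EUR", "AFR")))
  expect_equal(select_individuals(p, "EUR", 0.40), c("b", "c"))
  expect_equal(select_individuals(p, "EUR", 0), c("a", "b", "c"))
  expect_warning(sel <- select_individuals(p, "EUR", 0.99), "no individuals")
  expect_length(sel, 0)
})

test_that("masking keeps exactly the target-ancestry material", {
  h <- fix_history_single_pulse(t = 8, m = 0.25)
  map <- toy_genetic_map(2, 1)
  co <- simulate_tracts(h, map, n_hap = 20, pop_size = Inf, seed = 14)
  fm <- allele_frequency_model(uniform_sites(map, 0.5),
                               F = c(EUR = 0.1, AFR = 0.1, NAM = 0.1),
                               seed = 15)
  pan <- simulate_genotypes(co, fm, seed = 16)
  mk <- mask_panel(pan, ancestry = "AFR")
  # every surviving allele overlies AFR truth; everything else is missing
  expect_true(all(mk$truth[!is.na(mk$geno)] == "AFR"))
  expect_true(all(is.na(mk$geno[mk$truth != "AFR"])))
  # haplotype fully of target ancestry is unchanged
  full <- which(colSums(mk$truth == "AFR") == nrow(mk$truth))
  if (length(full))
    expect_equal(mk$geno[, full], pan$geno[, full])
  expect_equal(unname(attr(mk, "unmasked_sites")),
               unname(colSums(mk$truth == "AFR")))
})

test_that("pairwise ASD matches per-locus enumeration", {
  # individuals (AA/AB, AB/AB, AA/BB): per-locus 0.5, 0, 1 -> mean 0.5
  geno <- cbind(c(0, 0, 0), c(0, 1, 0),   # ind 1 haplotypes
                c(0, 1, 1), c(1, 0, 1))   # ind 2 haplotypes
  sites <- data.frame(chrom = "chr1", bp = 1:3, cM = 1:3)
  pan <- haplotype_panel(geno, sites)
  d <- pairwise_asd(pan, "genotype")
  expect_equal(d$D["1", "2"], 0.5)
  expect_equal(diag(d$D), c(0, 0), ignore_attr = TRUE)
  # identical genotypes -> 0; opposite homozygotes everywhere -> 1
  pan2 <- haplotype_panel(cbind(geno[, 1:2], geno[, 1:2]), sites)
  expect_equal(pairwise_asd(pan2, "genotype")$D["1", "2"], 0)
  pan3 <- haplotype_panel(cbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                          data.frame(chrom = "chr1", bp = 1:2, cM = 1:2))
  expect_equal(pairwise_asd(pan3, "genotype")$D["1", "2"], 1)
})

test_that("ASD is a bounded symmetric dissimilarity with overlap control", {
  set.seed(17)
  geno <- matrix(rbinom(400, 1, 0.4), nrow = 20)
  geno[sample(400, 60)] <- NA
  pan <- haplotype_panel(geno, data.frame(chrom = "chr1", bp = 1:20,
                                          cM = 1:20))
  d <- pairwise_asd(pan, "haplotype", min_overlap = 5)
  expect_true(isSymmetric(d$D))
  expect_true(all(d$D >= 0 & d$D <= 1, na.rm = TRUE))
  expect_true(all(is.na(d$D[d$overlap < 5] )))
  # permutation equivariance
  perm <- sample(ncol(geno))
  d2 <- pairwise_asd(haplotype_panel(geno[, perm],
                                     pan$sites), "haplotype",
                     min_overlap = 5)
  expect_equal(unname(d2$D), unname(d$D[perm, perm]))
})

test_that("classical MDS reproduces Euclidean configurations", {
  # 3 collinear points, distances 1, 1, 2: exact 1-D recovery up to sign
  D <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  m <- classical_mds(D, k = 1)
  x <- m$points[, 1]
  expect_equal(abs(diff(sort(x))), c(1, 1), tolerance = 1e-9)
  # random Euclidean input: pairwise distances reconstructed to 1e-9
  set.seed(18)
  pts <- matrix(rnorm(30), ncol = 3)
  D2 <- as.matrix(dist(pts))
  m2 <- classical_mds(D2, k = 3)
  expect_equal(as.matrix(dist(m2$points)), D2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # duplicate items embed at identical coordinates
  D3 <- as.matrix(dist(pts[c(1, 1, 2, 3, 4), ]))
  m3 <- classical_mds(D3, k = 2)
  expect_equal(m3$points[1, ], m3$points[2, ], tolerance = 1e-9)
  expect_error(classical_mds(D, k = 3), "positive eigenvalues")
})

test_that("haploid Weir-Cockerham FST behaves at the calibration points", {
  # fixed differences at every locus
  expect_equal(wc_fst(matrix(1, 10, 6), matrix(0, 10, 6))$theta_w, 1)
  # same population: |theta| < 0.01 at 5000 loci, 50 + 50 haplotypes
  sites <- uniform_sites(toy_genetic_map(5, 1), 0.1)
  fm <- allele_frequency_model(sites, F = c(P = 0), seed = 19)
  set.seed(20)
  g1 <- sapply(1:50, function(i) rbinom(nrow(sites), 1, fm$p["P", ]))
  g2 <- sapply(1:50, function(i) rbinom(nrow(sites), 1, fm$p["P", ]))
  expect_lt(abs(wc_fst(g1, g2)$theta_w), 0.01)
  # Balding-Nichols F = 0.05 panels -> theta in [0.03, 0.07]
  fm2 <- allele_frequency_model(sites, F = c(P1 = 0.05, P2 = 0.05),
                                seed = 21)
  set.seed(22)
  h1 <- sapply(1:50, function(i) rbinom(nrow(sites), 1, fm2$p["P1", ]))
  h2 <- sapply(1:50, function(i) rbinom(nrow(sites), 1, fm2$p["P2", ]))
  th <- wc_fst(h1, h2)$theta_w
  expect_gt(th, 0.03)
  expect_lt(th, 0.07)
  # invariance under allele relabeling
  expect_equal(wc_fst(1 - h1, 1 - h2)$theta_w, th, tolerance = 1e-12)
  expect_error(wc_fst(matrix(0, 5, 4), matrix(0, 5, 4)), "monomorphic")
})

test_that("aspca_mds reduces to plain ASD + MDS on unmasked input", {
  set.seed(23)
  sites <- data.frame(chrom = "chr1", bp = 1:60, cM = (1:60) / 10)
  g <- matrix(rbinom(60 * 10, 1, 0.5), nrow = 60)
  pan <- haplotype_panel(g[, 1:6], sites)
  ref <- haplotype_panel(g[, 7:10], sites)
  mm <- aspca_mds(pan, ref, k = 2, min_overlap = 10)
  direct <- classical_mds(pairwise_asd(
    haplotype_panel(g, sites), "haplotype")$D, k = 2)
  # same configuration up to axis sign
  for (j in 1:2)
    expect_equal(abs(mm$points[, j]), abs(unname(direct$points[, j])),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a masked haplotype identical to a reference co-embeds with it", {
  set.seed(24)
  sites <- data.frame(chrom = "chr1", bp = 1:80, cM = (1:80) / 10)
  refs <- matrix(rbinom(80 * 8, 1, 0.5), nrow = 80)
  masked <- haplotype_panel(refs[, 1, drop = FALSE], sites)
  mm <- aspca_mds(masked, haplotype_panel(refs, sites), k = 2,
                  min_overlap = 10)
  w <- mm$which
  i_m <- which(w$panel == "masked")
  i_r <- which(w$panel != "masked")[1]
  expect_equal(mm$points[i_m, ], mm$points[i_r, ], tolerance = 1e-9)
})

test_that("masked haplotypes embed near their true subcontinental source", {
  sites <- uniform_sites(toy_genetic_map(4, 1), 0.1)
  fm0 <- allele_frequency_model(sites, F = c(EUR = 0.15), seed = 25)
  fm <- allele_frequency_model(sites,
                               F = c(EUR1 = 0.01, EUR2 = 0.01, AFR = 0.25),
                               p0 = fm0$p["EUR", ], seed = 26)
  map <- toy_genetic_map(4, 1)
  mk_adm <- function(sub, seed) {
    h <- build_history(setNames(c(0.8, 0.2), c(sub, "AFR")), T_max = 15)
    co <- simulate_tracts(h, map, n_hap = 20, pop_size = Inf, seed = seed)
    mask_panel(simulate_genotypes(co, fm, seed = seed + 1),
               ancestry = sub)
  }
  ma <- mk_adm("EUR1", 27)
  mb <- mk_adm("EUR2", 29)
  set.seed(31)
  r1 <- sapply(1:30, function(i) rbinom(nrow(sites), 1, fm$p["EUR1", ]))
  r2 <- sapply(1:30, function(i) rbinom(nrow(sites), 1, fm$p["EUR2", ]))
  masked <- haplotype_panel(cbind(ma$geno, mb$geno), sites)
  mm <- aspca_mds(masked, list(EUR1 = haplotype_panel(r1, sites),
                               EUR2 = haplotype_panel(r2, sites)),
                  k = 2, min_overlap = 500)
  pts <- mm$points
  w <- mm$which
  c1 <- colMeans(pts[w$panel == "EUR1", , drop = FALSE])
  c2 <- colMeans(pts[w$panel == "EUR2", , drop = FALSE])
  mpts <- pts[w$panel == "masked", , drop = FALSE]
  truth <- rep(c("EUR1", "EUR2"), each = 20)
  d1 <- sqrt(rowSums(sweep(mpts, 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(mpts, 2, c2)^2))
  acc <- mean(ifelse(d1 < d2, "EUR1", "EUR2") == truth)
  expect_gte(acc, 0.8)
})
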