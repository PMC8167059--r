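# a confidence-map-like grid where each backbone atom of one residue sits at
# a voxel center surrounded (within `radius`) only by voxels of a chosen value
residue_on_patches <- function(values, radius = 1.0) {
  vals <- array(0, dim = c(24, 24, 24))
  pos <- list(N = c(5, 12, 12), CA = c(12, 12, 12), C = c(19, 12, 12))
  m <- density_map(vals)
  for (i in seq_along(pos)) {
    idx <- voxels_within_radius(m, pos[[i]], radius + 0.6)
    vals[idx + 1L] <- values[i]
  }
  atoms <- data.frame(chain = "A", resno = 1, insert = "", resid = "VAL",
                      elety = names(pos), elesy = c("N", "C", "C"),
                      x = vapply(pos, `[`, 0, 1),
                      y = vapply(pos, `[`, 0, 2),
                      z = vapply(pos, `[`, 0, 3),
                      stringsAsFactors = FALSE)
  list(map = density_map(vals), model = as_atomic_model(atoms))
}

test_that("residue score is the mean of its backbone atom confidences", {
  # per-atom confidences N = 0.0, CA = 1.0, C = 1.0 average to 0.67
  s1 <- residue_on_patches(c(0, 1, 1))
  r1 <- score_model(s1$map, s1$model)
  expect_equal(unname(r1$atom_scores[[1]][c("N", "CA", "C")]), c(0, 1, 1))
  expect_equal(round(r1$score, 2), 0.67)
  # per-atom confidences CA = 1.0, N = 1.0, carbonyl C = 0.75 average to 0.92
  s2 <- residue_on_patches(c(1, 1, 0.75))
  r2 <- score_model(s2$map, s2$model)
  expect_equal(unname(r2$atom_scores[[1]]["C"]), 0.75)
  expect_equal(round(r2$score, 2), 0.92)
  # all atoms at 1.0 average to exactly 1.0
  s3 <- residue_on_patches(c(1, 1, 1))
  expect_equal(score_model(s3$map, s3$model)$score, 1.0)
})

test_that("atom aggregation respects order statistics over the neighborhood", {
  m <- density_map(array(withr::with_seed(31, stats::runif(20^3)),
                         dim = c(20, 20, 20)))
  pts <- matrix(withr::with_seed(32, stats::runif(3000, 2, 17)), ncol = 3)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    idx <- voxels_within_radius(m, p, 1.0)
    if (nrow(idx) == 0L) next
    v <- map_value_at(m, idx)
    a_max <- as.numeric(atom_score(m, p, scoring_config(aggregation = "max")))
    a_mean <- as.numeric(atom_score(m, p, scoring_config(aggregation = "mean")))
    a_near <- as.numeric(atom_score(m, p, scoring_config(aggregation = "nearest")))
    expect_identical(a_max, max(v))
    expect_identical(a_mean, mean(v))
    expect_true(a_max >= a_mean && a_mean >= min(v))
    expect_true(a_near %in% v)
  }
})

test_that("atoms outside the grid score 0 and are flagged", {
  m <- density_map(array(1, dim = c(10, 10, 10)))
  s <- atom_score(m, c(50, 50, 50))
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "out_of_grid"))
  # inside the grid but with no voxel center within the radius: nearest value
  m$values[6, 6, 6] <- 0.4
  s2 <- atom_score(m, c(5.2, 5.2, 5.2), scoring_config(association_radius = 0.2))
  expect_identical(as.numeric(s2), 0.4)
  expect_false(attr(s2, "out_of_grid"))
})

test_that("model scoring recovers in-density and mistraced residues", {
  for (seed in c(101, 102)) {
    sc <- synthetic_scene(seed = seed, amplitude = 10, displace = c(4, 5),
                          n_residues = 12)
    cm <- confidence_map(sc$noisy_map)
    s <- score_model(cm, sc$model)
    expect_identical(nrow(s), 12L)
    expect_true(all(s$score >= 0 & s$score <= 1))
    expect_true(all(s$score[s$resno %in% c(4, 5)] <= 0.1))
    expect_true(all(s$score[!s$resno %in% c(4, 5)] >= 0.99))
    # every score is exactly the mean of its atom scores
    expect_true(all(vapply(seq_len(nrow(s)), function(i)
      abs(s$score[i] - mean(s$atom_scores[[i]])) < 1e-12, logical(1))))
  }
})

test_that("scores are invariant to storage-axis permutation of the map", {
  sc <- synthetic_scene(seed = 9, displace = 5)
  cm <- confidence_map(sc$noisy_map)
  direct <- score_model(cm, sc$model)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc_permuted(cm, f, c(3L, 1L, 2L))
  permuted <- score_model(read_density_map(f), sc$model)
  expect_equal(permuted$score, direct$score, tolerance = 1e-6)
})

test_that("raising every confidence never lowers a residue score", {
  sc <- synthetic_scene(seed = 10, displace = 6)
  cm <- confidence_map(sc$noisy_map)
  s1 <- score_model(cm, sc$model)
  up <- cm
  up$values <- 1 - (1 - cm$values) / 2
  s2 <- score_model(up, sc$model)
  expect_true(all(s2$score >= s1$score - 1e-12))
})

test_that("non-confidence maps are scored with a warning, unclamped", {
  sc <- synthetic_scene(seed = 11)
  expect_warning(s <- score_model(sc$noisy_map, sc$model), "confidence")
  expect_gt(max(s$score), 1)   # raw density values pass through
})

test_that("chain z-scores follow the per-chain mean/sd definition", {
  base <- data.frame(chain = "A", resno = 1:5, insert = "", resid = "ALA",
                     category = "protein", n_atoms_scored = 3L,
                     score = c(0.2, 0.4, 0.6, 0.8, 1.0), z_score = NA_real_,
                     out_of_grid = FALSE, stringsAsFactors = FALSE)
  z <- chain_zscores(base)
  expect_equal(z$z_score, (base$score - mean(base$score)) / stats::sd(base$score))

  flat <- base; flat$score <- rep(0.9, 5)
  expect_identical(chain_zscores(flat)$z_score, rep(0, 5))

  spike <- base; spike$score <- c(1, 1, 1, 1, 0)
  zs <- chain_zscores(spike)$z_score
  expect_identical(which.min(zs), 5L)

  # waters do not enter the chain statistics
  wat <- base; wat$category[5] <- "water"
  zw <- chain_zscores(wat)
  expect_true(is.na(zw$z_score[5]))
  expect_equal(zw$z_score[1:4],
               (wat$score[1:4] - mean(wat$score[1:4])) / stats::sd(wat$score[1:4]))
})

test_that("the scores CSV has one row per residue at 3-decimal precision", {
  sc <- synthetic_scene(seed = 12, n_residues = 3)
  s <- score_model(confidence_map(sc$noisy_map), sc$model)
  s$score <- c(0.8333333, 1, 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(s, f)
  expect_identical(length(readLines(f)), 4L)
  back <- utils::read.csv(f, colClasses = c(insertion_code = "character"))
  expect_identical(back$residue_number, s$resno)
  expect_identical(back$score, c(0.833, 1.000, 0.500))
})

test_that("the Chimera attribute file obeys the defattr grammar", {
  s <- data.frame(chain = c("A", "A", "B"), resno = c(107L, 52L, 3L),
                  insert = c("", "B", ""), resid = "ALA",
                  category = "protein", n_atoms_scored = 3L,
                  score = c(0.8333333, 0.25, 1), z_score = NA_real_,
                  out_of_grid = FALSE, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".defattr")
  write_chimera_attributes(s, "fdr_score", f)
  lines <- readLines(f)
  expect_identical(lines[4L], "\t:107.A\t0.833")
  expect_identical(lines[5L], "\t:52B.A\t0.250")
  parsed <- parse_defattr(f)
  expect_identical(parsed$resno, s$resno)
  expect_identical(parsed$chain, s$chain)
  expect_equal(parsed$value, round(s$score, 3))
  expect_error(write_chimera_attributes(s, "2bad name", f), "invalid")
})
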