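test_that("cohort size, prevalence and determinism", {
  cfg <- cohort_config(n_lesions = 515, noncr_prevalence = 0.2, seed = 7)
  cohort <- generate_cohort(cfg, images = FALSE)
  expect_equal(length(cohort), 515)
  n_noncr <- sum(vapply(cohort, `[[`, "", "label") == "nonCR")
  # binomial band around 103
  expect_lt(abs(n_noncr - 103), 3 * sqrt(515 * 0.2 * 0.8))

  again <- generate_cohort(cfg, images = FALSE)
  expect_identical(clinical_table(cohort), clinical_table(again))

  cfg2 <- cohort_config(n_lesions = 2000, noncr_prevalence = 0.5, seed = 3)
  c2 <- generate_cohort(cfg2, images = FALSE)
  frac <- mean(vapply(c2, `[[`, "", "label") == "nonCR")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))

  expect_error(cohort_config(noncr_prevalence = 0), "prevalence")
  expect_error(cohort_config(noncr_prevalence = 1.2), "prevalence")
})

test_that("lesion geometry honours the requested diameter", {
  les <- generate_lesion(list(diameter_cm = 1.2, label = "CR"), seed = 5)
  fv <- extract_features(window_scale(les$pre_image), les$tumor_mask)
  d <- unname(fv["geometry.max_diameter_mm"])
  expect_gte(d, 10); expect_lte(d, 14)
  # masks binary, ablation zone contains the tumor, grids shared
  expect_true(all(les$tumor_mask$values %in% 0:1))
  expect_equal(sum(les$tumor_mask$values *
                     (1 - les$ablation_mask$values)), 0)
  expect_equal(dim(les$pre_image$values), dim(les$post_image$values))
  expect_error(generate_lesion(list(diameter_cm = 3, label = "CR",
                                    extent_mm = 20), seed = 1),
               "exceeds")
})

test_that("generated images are seeded-deterministic", {
  a <- generate_lesion(list(diameter_cm = 1.0, label = "nonCR"), seed = 9)
  b <- generate_lesion(list(diameter_cm = 1.0, label = "nonCR"), seed = 9)
  expect_identical(a$post_image$values, b$post_image$values)
  expect_identical(a$tumor_mask$values, b$tumor_mask$values)
})

test_that("residual wedge appears only in non-CR ablation zones", {
  # same seed: CR and non-CR lesions differ only through the wedge
  cr <- generate_lesion(list(diameter_cm = 1.4, label = "CR",
                             margin_mm = 5), seed = 11)
  nc <- generate_lesion(list(diameter_cm = 1.4, label = "nonCR",
                             margin_mm = 5), seed = 11)
  abl <- cr$ablation_mask$values > 0
  diff <- abs(cr$post_image$values - nc$post_image$values) > 1e-9
  expect_gt(sum(diff), 0)
  # wedge texture is tumor-like (bright) relative to the ablation edge
  expect_gt(mean(nc$post_image$values[diff]),
            mean(cr$post_image$values[diff]))
  # zero residual effect removes the image-level class difference
  nc0 <- generate_lesion(list(diameter_cm = 1.4, label = "nonCR",
                              margin_mm = 5, residual_effect = 0),
                         seed = 11)
  cr0 <- generate_lesion(list(diameter_cm = 1.4, label = "CR",
                              margin_mm = 5, residual_effect = 0),
                         seed = 11)
  expect_equal(max(abs(nc0$post_image$values - cr0$post_image$values)), 0)
})

test_that("a single latent subregion gives one texture population", {
  les <- generate_lesion(list(diameter_cm = 1.4, label = "CR",
                              latent_subregions = 1), seed = 2)
  pre <- window_scale(les$pre_image)
  v <- pre$values[les$tumor_mask$values > 0]
  # unimodal: interior voxels stay within one narrow population
  expect_lt(diff(quantile(v, c(0.1, 0.9))), 30)
})

test_that("clinical covariates are moment-matched and class-shifted", {
  cfg <- cohort_config(n_lesions = 1200, noncr_prevalence = 0.4, seed = 13)
  tab <- clinical_table(generate_cohort(cfg, images = FALSE))
  expect_equal(nrow(tab), 1200)
  expect_lt(abs(mean(tab$age) - 57.9), 1.5)
  # CA19-9 stochastically larger in non-CR
  expect_gt(mean(tab$ca199[tab$label == "nonCR"]),
            mean(tab$ca199[tab$label == "CR"]))
  expect_gt(wilcox.test(ca199 ~ label, data = tab)$statistic, 0)
  expect_true(all(tab$nodule_size <= 3 & tab$nodule_size > 0))
  # lower lobes over-represented in non-CR (location effect)
  lower <- tab$lobe %in% c("RLL", "LLL")
  expect_gt(mean(lower[tab$label == "nonCR"]),
            mean(lower[tab$label == "CR"]))
})

test_that("splits reproduce 412/103 and are deterministic", {
  cfg <- cohort_config(n_lesions = 515, seed = 7)
  cohort <- generate_cohort(cfg, images = FALSE)
  sp <- split_cohort(cohort, 0.8, seed = 1)
  expect_equal(length(sp$train), 412)
  expect_equal(length(sp$test), 103)
  # both partitions contain both labels
  expect_equal(length(unique(vapply(sp$train, `[[`, "", "label"))), 2)
  expect_equal(length(unique(vapply(sp$test, `[[`, "", "label"))), 2)

  sp2 <- split_cohort(cohort, 0.8, seed = 1)
  expect_identical(vapply(sp$train, `[[`, "", "lesion_id"),
                   vapply(sp2$train, `[[`, "", "lesion_id"))

  ten <- cohort[1:10]
  sp10 <- split_cohort(ten, 0.8, seed = 2)
  expect_equal(length(sp10$train), 8)
  expect_equal(length(sp10$test), 2)
  expect_error(split_cohort(cohort[1], 0.8, 1), "2 cases")
  expect_error(split_cohort(ten, 1.2, 1), "ratio")
})

test_that("cohorts round-trip through NIfTI + CSV + manifest", {
  cfg <- cohort_config(n_lesions = 2, seed = 23,
                       diameter_range_cm = c(0.8, 1.2))
  cohort <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  manifest <- write_cohort(cohort, dir)
  expect_equal(manifest$n_lesions, 2)
  expect_equal(length(manifest$lesions), 2)
  expect_equal(nrow(read.csv(file.path(dir, "clinical.csv"))), 2)
  back <- read_cohort(dir)
  for (i in 1:2) {
    expect_equal(sum(back[[i]]$tumor_mask$values),
                 sum(cohort[[i]]$tumor_mask$values))
    expect_equal(sum(back[[i]]$ablation_mask$values),
                 sum(cohort[[i]]$ablation_mask$values))
    expect_equal(back[[i]]$label, cohort[[i]]$label)
    expect_equal(back[[i]]$pre_image$spacing, cohort[[i]]$pre_image$spacing)
  }
  unlink(dir, recursive = TRUE)
})
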