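test_that("apparent unbound fraction is the receiver/donor ratio", {
  expect_equal(fu_from_red(dialysis_measurement("plasma", 1.0, 0.002)),
               0.002)
  expect_equal(fu_from_red(dialysis_measurement("plasma", 0.8, 0.8)), 1)
  zero <- dialysis_measurement("brain_homogenate", 1, 0, 4)
  expect_error(fu_from_red(zero), "indeterminate")
  expect_warning(fl <- fu_from_red(zero, zero_receiver = "floor"), "floor")
  expect_gt(fl, 0)
})

test_that("dilution correction inverts the forward dilution model exactly", {
  # forward: fu_app = D.fu/(1 + (D-1).fu); correction must be its inverse
  fwd <- function(fu, d) d * fu / (1 + (d - 1) * fu)
  for (fu in c(0.0005, 0.006, 0.05, 0.3, 0.9, 1)) {
    for (d in c(1, 2, 4, 10)) {
      expect_equal(correct_fu_dilution(fwd(fu, d), d), fu,
                   tolerance = 1e-12)
    }
  }
  expect_equal(correct_fu_dilution(0.3, 1), 0.3)
  expect_equal(correct_fu_dilution(1, 7), 1)
  expect_equal(correct_fu_dilution(fwd(0.0005, 4), 4), 0.0005)
  # monotone increasing in the apparent fraction
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(correct_fu_dilution(grid, 4)) > 0))
  expect_error(correct_fu_dilution(0, 4))
  expect_error(correct_fu_dilution(0.5, 0.5))
})

test_that("estimate_binding corrects brain homogenate but not plasma", {
  m <- list(dialysis_measurement("plasma", 1, 0.006, 1),
            dialysis_measurement("brain_homogenate", 1, 0.001997, 4))
  res <- estimate_binding(m)
  expect_equal(res$fu_corrected[1], res$fu_apparent[1])
  expect_lt(res$fu_corrected[2], res$fu_apparent[2])
  expect_equal(res$fu_corrected[2], 0.0005, tolerance = 1e-3)
})

test_that("Kp, Kp,uu and DA reproduce the printed study values", {
  expect_equal(as.numeric(compute_kp(23, 100)), 0.23)
  expect_equal(as.numeric(compute_kp(5, 5)), 1)
  expect_error(compute_kp(1, 0), "positive")

  # wild-type: Kp 0.23 with fu_brain 0.0005, fu_plasma 0.006 -> 0.02
  expect_equal(round(compute_kpuu(0.23, 0.0005, 0.006), 2), 0.02)
  # efflux-knockout: Kp 12.12 -> 1.01
  expect_equal(round(compute_kpuu(12.12, 0.0005, 0.006), 2), 1.01)
  expect_equal(compute_kpuu(0.4, 0.01, 0.01), 0.4)  # binding symmetry

  expect_equal(compute_da(12.12, 0.23), 52.7, tolerance = 1e-3)
  expect_equal(compute_da(3, 3), 1)
  expect_equal(compute_da(5, 2) * compute_da(2, 5), 1)
  expect_error(compute_da(1, 0))
})

test_that("partition metrics are invariant to global concentration rescaling", {
  t <- seq(0, 15, by = 0.1)
  mk <- function(scale) {
    list(run_nca(simple_profile(t, scale * 2000 * exp(-0.3 * t), "plasma")),
         run_nca(pk_profile("fix01", "fixture", "brain", t,
                            scale * 460 * exp(-0.3 * t))))
  }
  ps1 <- partition_summary(mk(1), 0.0005, 0.006, "fixture")
  ps2 <- partition_summary(mk(1000), 0.0005, 0.006, "fixture")
  expect_equal(ps1$kp, ps2$kp)
  expect_equal(ps1$kp_uu, ps2$kp_uu)
  expect_equal(ps1$kp, 0.23, tolerance = 1e-6)
  # internal consistency: kp_uu = kp . fu_brain/fu_plasma
  expect_equal(ps1$kp_uu, ps1$kp * 0.0005 / 0.006)
})

test_that("regional partition table recovers constructed true ratios", {
  # three regions, two groups, known per-subject ratios
  regions <- c("tumor_core", "tumor_rim", "normal_brain")
  true_kp <- c(alone_tumor_core = 1.2, alone_tumor_rim = 0.3,
               alone_normal_brain = 0.1, combo_tumor_core = 4.8,
               combo_tumor_rim = 3.0, combo_normal_brain = 1.0)
  rows <- expand.grid(subject = 1:3, region = regions,
                      group = c("alone", "combo"),
                      stringsAsFactors = FALSE)
  plasma_conc <- 100 + 10 * rows$subject  # subject-specific plasma level
  regional <- data.frame(
    subject_id = paste0(rows$group, rows$subject), group = rows$group,
    region = rows$region,
    concentration = plasma_conc *
      true_kp[paste(rows$group, rows$region, sep = "_")])
  plasma <- data.frame(subject_id = paste0(rows$group, rows$subject),
                       group = rows$group, concentration = plasma_conc)
  plasma <- unique(plasma)
  tab <- regional_partition_table(regional, plasma,
                                  reference_group = "alone")
  got <- setNames(tab$kp, paste(tab$group, tab$region, sep = "_"))
  expect_equal(got[names(true_kp)], true_kp, tolerance = 1e-12)
  # fold increase is against normal brain of the drug-alone group
  expect_equal(tab$fold_increase[tab$group == "alone" &
                                   tab$region == "normal_brain"], 1)
  expect_equal(tab$fold_increase[tab$group == "combo" &
                                   tab$region == "normal_brain"], 10)
  expect_equal(tab$fold_increase[tab$group == "combo" &
                                   tab$region == "tumor_core"], 48)
  # per-subject rescaling leaves ratios unchanged
  regional2 <- regional
  sel <- regional2$subject_id == "alone1"
  regional2$concentration[sel] <- regional2$concentration[sel] * 2
  plasma2 <- plasma
  plasma2$concentration[plasma2$subject_id == "alone1"] <-
    plasma2$concentration[plasma2$subject_id == "alone1"] * 2
  tab2 <- regional_partition_table(regional2, plasma2,
                                   reference_group = "alone")
  expect_equal(tab2$kp, tab$kp)
  expect_error(regional_partition_table(regional, plasma,
                                        reference_group = "absent"),
               "not present")
})
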