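test_that("susceptible ceiling reproduces frozen values and its limits", {
  ext <- scn_ext(); perm <- scn_perm()
  # frozen from 30-digit arithmetic on the closed form
  expect_equal(susceptible_ceiling(ext$rates, ext$pulses, "without_factor"),
               4.8195154282368790, tolerance = 1e-13)
  expect_equal(susceptible_ceiling(perm$rates, perm$pulses, "with_factor"),
               10.7831963951803250, tolerance = 1e-13)

  # long-period limit: ceiling approaches the unpulsed equilibrium Pi/mu
  long <- pulse_params(T = 1e4, theta1 = 0.1, xi = 0.02)
  expect_equal(susceptible_ceiling(ext$rates, long, "without_factor"),
               ext$rates$Pi / ext$rates$mu, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:25) {
    r <- random_rates(); p <- random_pulses()
    zw <- susceptible_ceiling(r, p, "with_factor")
    zn <- susceptible_ceiling(r, p, "without_factor")
    expect_gt(zn, zw)                      # (1 - theta1) factor
    expect_lt(zn, r$Pi / r$mu + 1e-12)     # bounded by Pi/mu
    p2 <- pulse_params(T = p$T * 1.5, theta1 = p$theta1, xi = p$xi)
    expect_gt(susceptible_ceiling(r, p2, "without_factor"), zn)  # increasing in T
    expect_gt(susceptible_ceiling(r, p2, "with_factor"), zw)
  }
})

test_that("attractivity threshold reproduces both clearance variants", {
  sc <- scn_ext()
  expect_equal(attractivity_threshold(sc$rates, sc$pulses,
                                      "without_factor", "d_only"),
               0.6498244186, tolerance = 1e-9)
  expect_equal(attractivity_threshold(sc$rates, sc$pulses,
                                      "without_factor", "d_minus_b"),
               0.9131765117, tolerance = 1e-9)

  # both transmission routes removed: threshold vanishes
  r <- unclass(sc$rates); r$beta <- 1e-12; r$eta <- 1e-12
  expect_lt(attractivity_threshold(validate_rate_params(r), sc$pulses), 1e-9)

  # the environmental term is nonnegative, so the permanence threshold
  # never exceeds the attractivity threshold
  set.seed(63)
  for (i in 1:25) {
    rr <- random_rates(); pp <- random_pulses()
    for (zv in c("without_factor", "with_factor")) {
      expect_lte(permanence_threshold(rr, pp, zv),
                 attractivity_threshold(rr, pp, zv, "d_minus_b"))
    }
  }
})

test_that("permanence threshold reproduces both ceiling variants", {
  sc <- scn_perm()
  expect_equal(permanence_threshold(sc$rates, sc$pulses, "without_factor"),
               2.0644229137, tolerance = 1e-9)
  with_f <- permanence_threshold(sc$rates, sc$pulses, "with_factor")
  expect_equal(with_f, 2.0060093997, tolerance = 1e-9)
  expect_equal(round(with_f, 2), 2.01)

  # strictly increasing in beta
  vals <- sapply(c(1, 2, 4, 8), function(bb) {
    r <- unclass(sc$rates); r$beta <- bb
    permanence_threshold(validate_rate_params(r), sc$pulses)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("exposed lower bound and permanence floors are mutually consistent", {
  sc <- scn_perm()
  eb <- exposed_lower_bound(sc$rates, sc$pulses)
  expect_equal(eb, 0.0603605640, tolerance = 1e-8)
  # identity: Ebar = (mu/beta) (R1_lower_with - 1), so Ebar > 0 iff that
  # threshold exceeds one
  expect_equal(eb, sc$rates$mu / sc$rates$beta *
                 (permanence_threshold(sc$rates, sc$pulses, "with_factor") - 1),
               tolerance = 1e-13)

  fl <- persistence_floors(sc$rates, sc$pulses)
  q <- setNames(fl$value, fl$floor)
  a <- (1 - 0.5) * 2 + 0.5 * 1.3 + 0.3
  expect_equal(unname(q["q2"]), eb * exp(-a), tolerance = 1e-13)
  expect_equal(unname(q["q2"]), 0.0085877432, tolerance = 1e-8)
  expect_equal(unname(q[c("q1", "q3", "q4", "q5")]),
               c(0.0073141381, 0.0002868289, 0.0095083796, 0.0019975076),
               tolerance = 1e-6)
  expect_true(all(fl$valid))

  # degenerate routing: all-asymptomatic kills q3, all-symptomatic kills q4
  r <- unclass(sc$rates)
  r$theta <- 1
  expect_equal(subset(persistence_floors(validate_rate_params(r), sc$pulses),
                      floor == "q3")$value, 0)
  r$theta <- 0
  expect_equal(subset(persistence_floors(validate_rate_params(r), sc$pulses),
                      floor == "q4")$value, 0)

  # extinction-side parameters: exposed bound is negative, q2 flagged
  fl_ext <- persistence_floors(scn_ext()$rates, scn_ext()$pulses)
  expect_false(fl_ext$valid[fl_ext$floor == "q2"])
})

test_that("upsilon is the positive root of its quadratic", {
  sc <- scn_ext()
  cp <- critical_period_attract(sc$rates, sc$pulses)
  expect_equal(cp$upsilon, 3.7070932057, tolerance = 1e-9)
  expect_equal(cp$T_star, 0.2359735294, tolerance = 1e-9)

  # independent oracle: polyroot on A u^2 + (B + KA - BC) u - KBC
  K <- sc$rates$K
  roots <- polyroot(c(-K * cp$B * cp$C, cp$B + K * cp$A - cp$B * cp$C, cp$A))
  pos <- Re(roots[abs(Im(roots)) < 1e-10 & Re(roots) > 0])
  expect_equal(cp$upsilon, pos, tolerance = 1e-12)

  set.seed(67)
  for (i in 1:25) {
    r <- random_rates(); p <- random_pulses()
    A <- r$eta * r$Pi * (r$lambda1 + r$lambda2)
    B <- r$mu * (r$d - r$b)
    C <- (1 - r$theta) * r$varpi + r$theta * r$rho + r$mu
    disc <- (B + r$K * A - B * C)^2 + 4 * r$K * A * B * C
    expect_gt(disc, 0)  # always a real positive root
  }
})

test_that("critical vaccination fractions and period behave at their limits", {
  sc <- scn_ext()
  expect_equal(critical_vacc_fraction(sc$rates, sc$pulses, "attractivity"),
               0.6456288797, tolerance = 1e-9)

  perm <- scn_perm()
  expect_equal(critical_vacc_fraction(perm$rates, perm$pulses, "permanence"),
               0.6708372219, tolerance = 1e-9)
  expect_equal(critical_period_perm(perm$rates, perm$pulses),
               0.0639529200, tolerance = 1e-9)

  # T -> 0+: no time to rebuild susceptibles, critical fraction vanishes
  p0 <- pulse_params(T = 1e-8, theta1 = 0.13, xi = 0.02)
  expect_lt(critical_vacc_fraction(perm$rates, p0, "permanence"), 1e-6)

  # theta1 -> 0: critical period vanishes
  p1 <- pulse_params(T = 1, theta1 = 1e-10, xi = 0.02)
  expect_lt(critical_period_perm(perm$rates, p1), 1e-8)

  # weak-transmission parameters fail the applicability condition
  expect_error(critical_vacc_fraction(sc$rates, sc$pulses, "permanence"),
               "applicability")
})

test_that("permanence-critical controls are roots of the with-factor threshold", {
  perm <- scn_perm()
  th_star <- critical_vacc_fraction(perm$rates, perm$pulses, "permanence")
  p_at <- pulse_params(T = perm$pulses$T, theta1 = th_star, xi = perm$pulses$xi)
  expect_equal(permanence_threshold(perm$rates, p_at, "with_factor"), 1,
               tolerance = 1e-10)

  t_bar <- critical_period_perm(perm$rates, perm$pulses)
  p_tb <- pulse_params(T = t_bar, theta1 = perm$pulses$theta1,
                       xi = perm$pulses$xi)
  expect_equal(permanence_threshold(perm$rates, p_tb, "with_factor"), 1,
               tolerance = 1e-10)
})

test_that("threshold report aggregates every variant and survives JSON", {
  sc <- scn_perm()
  rep <- threshold_report(sc$rates, sc$pulses)
  expect_s3_class(rep, "threshold_report")
  expect_identical(sum(rep$quantity == "R1_star"), 4L)
  expect_identical(sum(rep$quantity == "zeta"), 2L)
  expect_equal(rep$value[rep$quantity == "R1_lower" &
                           rep$variant == "without_factor"],
               permanence_threshold(sc$rates, sc$pulses, "without_factor"))

  f <- tempfile(fileext = ".json")
  report_to_json(rep, f)
  back <- report_from_json(f)
  expect_equal(back$value, rep$value, tolerance = 1e-15)
  expect_identical(back$quantity, rep$quantity)

  # domain failures are reported as NA-with-note, not errors
  ext_rep <- threshold_report(scn_ext()$rates, scn_ext()$pulses)
  row <- ext_rep[ext_rep$quantity == "theta1_star_perm", ]
  expect_true(is.na(row$value))
  expect_match(row$note, "applicability")
})
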