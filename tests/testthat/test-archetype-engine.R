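# Rule-based archetypes: definitions, assignment, RR tables, and
# enumerative discovery.

test_that("the built-in rule set has 16 rules in 4/4/8 categories", {
  rules <- builtin_rules()
  expect_length(rules, 16)
  cats <- table(vapply(rules, `[[`, character(1), "category"))
  expect_identical(as.integer(cats[c("demographic", "behavioral",
                                     "socio_behavioral")]),
                   c(4L, 4L, 8L))
  expect_false(any(duplicated(names(rules))))
})

test_that("employed-youth-at-payday requires age 18-29, employment and payday proximity", {
  # age 22, employed, payday on the 28th, next visit on the 31st: 3 days off
  cl <- make_client(birth_date = as.Date("1998-03-01"),
                    employment = "employed", payday_day_of_month = 28L)
  v <- make_visits(days_late = c(0, 0), start = as.Date("2020-07-03"), gap = 28)
  a <- assign_archetypes(label_and_pair(v, cl), cl)
  expect_true(a$employed_youth_at_payday[1])
  # same schedule, age 35: no match
  cl2 <- make_client(birth_date = as.Date("1985-03-01"))
  a2 <- assign_archetypes(label_and_pair(v, cl2), cl2)
  expect_false(any(a2$employed_youth_at_payday))
  # unemployed youth: no match
  cl3 <- make_client(birth_date = as.Date("1998-03-01"),
                     employment = "unemployed",
                     payday_day_of_month = NA_integer_)
  a3 <- assign_archetypes(label_and_pair(v, cl3), cl3)
  expect_false(any(a3$employed_youth_at_payday))
})

test_that("one prior missed visit marks returning-after-disengagement but not late-twice", {
  cl <- make_client()
  v <- make_visits(days_late = c(30, 0, 0), gap = 60)
  a <- assign_archetypes(label_and_pair(v, cl), cl)
  # at the third visit the prior lateness sequence is (30, 0)
  expect_true(a$returning_after_disengagement[3])
  expect_false(a$late_twice[3])
  # two consecutive late prior visits trigger late-twice
  cl2 <- make_client("C2")
  v2 <- make_visits("C2", days_late = c(2, 5, 0), gap = 60)
  a2 <- assign_archetypes(label_and_pair(v2, cl2), cl2)
  expect_true(a2$late_twice[3])
  expect_false(a2$returning_after_disengagement[3])
})

test_that("demographic archetypes partition visits by age and sex", {
  # a 23-year-old woman is AGYW
  cl <- make_client(birth_date = as.Date("1997-01-15"))
  v <- make_visits(days_late = 0, start = as.Date("2020-06-01"))
  a <- assign_archetypes(label_and_pair(v, cl), cl)
  expect_identical(a$demographic, "agyw")
  # age 25 exactly is adult (boundary decision)
  cl25 <- make_client(birth_date = as.Date("1995-06-01"))
  a25 <- assign_archetypes(label_and_pair(v, cl25), cl25)
  expect_identical(a25$demographic, "adult_female")
  # every synthetic visit matches exactly one demographic archetype
  co <- default_cohort()
  aa <- assign_archetypes(co$labeled, co$cohort$clients)
  demo <- as.matrix(aa[c("adult_female", "adult_male", "agyw", "abym")])
  expect_true(all(rowSums(demo) == 1))
})

test_that("super-green needs a punctual history and company at home", {
  cl <- make_client(household_size_others = 4L)
  v <- make_visits(days_late = c(0, 3, 1), gap = 60)
  a <- assign_archetypes(label_and_pair(v, cl), cl)
  # needs at least two prior visits, all within 3 days
  expect_identical(a$super_green, c(FALSE, FALSE, TRUE))
  # living alone disqualifies
  alone <- make_client(household_size_others = 0L)
  a2 <- assign_archetypes(label_and_pair(v, alone), alone)
  expect_false(any(a2$super_green))
})

test_that("distance rules leave exactly 20 minutes unmatched", {
  v <- make_visits(days_late = c(5, 5, 5), gap = 60)
  at <- function(mins) {
    cl <- make_client(travel_time_min = mins, household_size_others = 0L)
    assign_archetypes(label_and_pair(v, cl), cl)
  }
  near <- at(10); border <- at(20); far <- at(30)
  expect_true(near$live_close_always_late[3])
  expect_false(border$live_close_always_late[3])
  expect_false(far$live_close_always_late[3])
  expect_true(far$lone_ranger[3])
  expect_false(border$lone_ranger[3])
  expect_false(near$lone_ranger[3])
})

test_that("the archetype table reproduces published relative risks from printed counts", {
  checks <- list(
    # behavioral, routine-EMR cohort: late twice vs prompt and loyal
    list(c(15932, 97986, 59099, 652595), 1.80),
    # socio-behavioral, survey cohort, vs super green
    list(c(93, 501, 239, 2313), 1.80),    # prepared and late
    list(c(221, 1478, 239, 2313), 1.45),  # lone ranger
    list(c(184, 1194, 239, 2313), 1.49)   # disillusioned disclosers
  )
  for (ch in checks) {
    r <- crude_rr(do.call(two_by_two, as.list(ch[[1]])))
    expect_equal(round(r$rr, 2), ch[[2]])
  }
})

test_that("archetype tables agree with the stats module on the same counts", {
  co <- default_cohort()
  aa <- assign_archetypes(co$labeled, co$cohort$clients)
  tab <- archetype_table(aa, reference = "prompt_and_loyal",
                         archetypes = c("late_twice",
                                        "returning_after_disengagement"))
  ref <- tab[tab$archetype == "prompt_and_loyal", ]
  for (arch in c("late_twice", "returning_after_disengagement")) {
    row <- tab[tab$archetype == arch, ]
    manual <- crude_rr(two_by_two(row$n_iit, row$n_visits,
                                  ref$n_iit, ref$n_visits))
    expect_equal(row$rr, manual$rr)
    expect_equal(row$ci_low, manual$ci_low)
    expect_equal(row$ci_high, manual$ci_high)
  }
})

test_that("an archetype compared with itself has RR exactly 1", {
  co <- default_cohort()
  aa <- assign_archetypes(co$labeled, co$cohort$clients)
  tab <- archetype_table(aa, reference = "prompt_and_loyal",
                         archetypes = "prompt_and_loyal")
  expect_identical(tab$rr[2], 1)
})

test_that("cross-stratified tables restrict to early months and use the demographic reference", {
  co <- default_cohort()
  aa <- assign_archetypes(co$labeled, co$cohort$clients)
  t7 <- archetype_table(aa, reference = "adult_female", restrict_months = 6,
                        cross_demographic = TRUE)
  expect_identical(t7$archetype[1], "adult_female")
  expect_true(any(grepl("agyw:", t7$archetype)))
  # restricted reference row counts only early visits
  early <- aa[!is.na(aa$iit_next_visit) & aa$time_on_art_months <= 6, ]
  expect_equal(t7$n_visits[1], sum(early$adult_female))
  expect_error(archetype_table(aa, reference = "no_such"), "not found")
})

test_that("discovery enumerates the full configuration space before pruning", {
  withr::with_seed(12, {
    n <- 300
    feats <- tibble::tibble(
      a = sample(c(TRUE, FALSE), n, TRUE),
      b = sample(c(TRUE, FALSE), n, TRUE),
      c = sample(c(TRUE, FALSE), n, TRUE),
      d = sample(c(TRUE, FALSE), n, TRUE)
    )
    y <- runif(n) < 0.2
  })
  seg <- discover_archetypes(feats, y, c("a", "b", "c", "d"), min_size = 1)
  # brute force: C(4,2) pairs x 4 configurations each
  expect_equal(attr(seg, "n_configs_evaluated"), choose(4, 2) * 4)
  # configurations of any one pair partition the visits
  ab <- seg[seg$variables == "a & b", ]
  expect_equal(sum(ab$n_visits), n)
})

test_that("contradictory configurations carry no support and are dropped", {
  feats <- tibble::tibble(
    lives_alone = c(TRUE, FALSE, FALSE),
    household_2plus = c(FALSE, TRUE, TRUE)
  )
  y <- c(TRUE, FALSE, TRUE)
  seg <- discover_archetypes(feats, y, c("lives_alone", "household_2plus"),
                             min_size = 1)
  expect_false(any(seg$values == "lives_alone=TRUE & household_2plus=TRUE"))
})

test_that("a planted high-risk configuration ranks first", {
  withr::with_seed(2027, {
    n <- 5000
    a <- sample(c(TRUE, FALSE), n, TRUE)
    b <- sample(c(TRUE, FALSE), n, TRUE)
    cNoise <- sample(c(TRUE, FALSE), n, TRUE)
    p <- ifelse(a & b, 0.24, 0.12)  # twice baseline risk in the (TRUE, TRUE) cell
    y <- runif(n) < p
  })
  seg <- discover_archetypes(tibble::tibble(a = a, b = b, c = cNoise), y,
                             c("a", "b", "c"), min_size = 50)
  expect_identical(seg$values[1], "a=TRUE & b=TRUE")
  expect_gt(seg$delta_vs_baseline[1], 0)
})

test_that("discovery input contracts are enforced", {
  feats <- tibble::tibble(a = c(TRUE, FALSE), big = c(1, 2))
  expect_error(discover_archetypes(feats, c(TRUE, FALSE), character(0)),
               "no key variables")
  expect_error(discover_archetypes(feats, c(TRUE, FALSE), "zz"),
               "not in features")
  expect_error(discover_archetypes(feats, c(TRUE, FALSE), "a", order = 2),
               "at least")
  many <- tibble::tibble(v = as.character(1:30), w = rep("x", 30))
  expect_error(discover_archetypes(many, rep(c(TRUE, FALSE), 15),
                                   c("v", "w"), min_size = 1),
               "more than 10 levels")
})
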