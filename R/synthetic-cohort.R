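# Synthetic cohort, clocks and beta matrices -------------------------------
#
# The generator emulates the study design the downstream stages assume: two
# co-located populations of 24 (12M/12F, half infected, urban/rural split),
# ages drawn from the printed group means/SDs, and beta matrices that carry
# a chronological-age signal through clock CpGs plus planted per-group
# acceleration shifts calibrated so that the *residual* group medians match
# the planted values after age adjustment.

#' Cohort design specification
#'
#' Defaults reproduce the study design: 24 individuals per group, 12 of each
#' sex, half infected (balanced by sex), ages Normal(39.2, 12.9) and
#' Normal(41.1, 14.0) truncated at 18 years, 20/24 rural in the
#' indigenous-role group and 0/24 in the admixed-role group, and planted
#' acceleration medians for the four age clocks.
#'
#' @param n_per_group Individuals per group.
#' @param group_names Labels; the first group plays the indigenous role, the
#'   second the admixed role.
#' @param sex_balance Females then males per group.
#' @param infected_fraction Infected fraction per group (must yield integer
#'   counts within each sex stratum).
#' @param age_mean,age_sd Per-group age distribution, years.
#' @param rural_counts Rural dwellers per group.
#' @param planted_accel_shifts Named list, estimator -> c(median shift group
#'   1, median shift group 2), in years (residual scale).
#' @param age_min Truncation bound, years.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 24,
                        group_names = c("groupA", "groupB"),
                        sex_balance = c(12, 12),
                        infected_fraction = 0.5,
                        age_mean = c(39.2, 41.1),
                        age_sd = c(12.9, 14.0),
                        rural_counts = c(20, 0),
                        planted_accel_shifts = default_planted_shifts(),
                        age_min = 18) {
  if (length(group_names) != 2) stop_acl("exactly two groups are supported")
  if (any(age_sd <= 0)) stop_acl("age SDs must be positive")
  if (n_per_group > 0) {
    if (sum(sex_balance) != n_per_group) {
      stop_acl("sex_balance must sum to n_per_group")
    }
    if (any(rural_counts > n_per_group)) {
      stop_acl("rural_counts exceed group size")
    }
  }
  structure(list(n_per_group = n_per_group, group_names = group_names,
                 sex_balance = sex_balance,
                 infected_fraction = infected_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 rural_counts = rural_counts,
                 planted_accel_shifts = planted_accel_shifts,
                 age_min = age_min),
            class = "cohort_spec")
}

#' Planted group-median acceleration shifts for the four age clocks
#'
#' The calibration profile of the generator: residual-scale group medians
#' (indigenous role, admixed role) in years for EEAA-, Hannum-, Pheno- and
#' Grim-type clocks.
#'
#' @return Named list of length-two numeric vectors.
#' @export
default_planted_shifts <- function() {
  list(EEAA           = c(1.26, -2.55),
       AgeAccelHannum = c(0.87, -1.67),
       AgeAccelPheno  = c(1.19, -2.62),
       AgeAccelGrim   = c(0.42, -1.16))
}

rnorm_truncated <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort metadata table
#'
#' Exact counts for group sizes, sex, infection status (balanced by sex) and
#' place of living; ages Normal truncated at `spec$age_min`; cell fractions
#' Dirichlet over seven blood cell types.  Deterministic per seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return A validated `sample_table` data frame.
#' @export
gen_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  cell_types <- c("cd8_naive", "cd8_exhausted", "plasmablast", "cd4",
                  "nk", "mono", "gran")
  empty <- data.frame(sample_id = character(0), population = character(0),
                      age = numeric(0), sex = character(0),
                      infected = logical(0), paraje = character(0))
  if (spec$n_per_group == 0) return(validate_sample_table(empty))
  with_seed(seed, {
    rows <- lapply(1:2, function(g) {
      n <- spec$n_per_group
      sex <- rep(c("F", "M"), times = spec$sex_balance)
      # infection balanced within each sex stratum
      inf <- logical(n)
      for (s in unique(sex)) {
        ns <- sum(sex == s)
        k <- spec$infected_fraction * ns
        if (abs(k - round(k)) > 1e-9) {
          stop_acl(sprintf(
            "infected_fraction %.3f does not give an integer count for %d %s",
            spec$infected_fraction, ns, s))
        }
        inf[which(sex == s)[seq_len(round(k))]] <- TRUE
      }
      paraje <- rep("urban", n)
      paraje[seq_len(spec$rural_counts[g])] <- "rural"
      data.frame(
        sample_id = sprintf("%s_%02d", spec$group_names[g], seq_len(n)),
        population = spec$group_names[g],
        age = rnorm_truncated(n, spec$age_mean[g], spec$age_sd[g],
                              spec$age_min),
        sex = sex, infected = inf, paraje = sample(paraje),
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    cf <- matrix(stats::rgamma(nrow(d) * length(cell_types), shape = 2),
                 nrow = nrow(d))
    cf <- cf / rowSums(cf)
    colnames(cf) <- paste0("cell_", cell_types)
    d <- cbind(d, as.data.frame(cf))
    validate_sample_table(d)
    d
  })
}

#' Generate a random linear clock definition
#'
#' Coefficients are drawn symmetrically around zero and rescaled, with the
#' intercept set so that beta values in `[0, 1]` can represent the full
#' adult age range 18-90 years after the output transform (a generated
#' clock is exactly invertible by [gen_betas()]).
#'
#' @param n_cpgs Number of CpGs (>= 1).
#' @param kind `"age"` or `"surrogate"`.
#' @param transform `"identity"` or `"horvath"`.
#' @param seed Integer RNG seed.
#' @param name Clock name.
#' @param age_range Representable target range, years.
#' @return A [clock_definition()].
#' @export
gen_clock <- function(n_cpgs, kind = c("age", "surrogate"),
                      transform = c("identity", "horvath"), seed,
                      name = sprintf("clock%d", n_cpgs),
                      age_range = c(10, 100)) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (n_cpgs < 1) stop_acl("n_cpgs must be >= 1")
  with_seed(seed, {
    cpgs <- sprintf("cg%08d", sample.int(1e8, n_cpgs))
    w <- stats::rnorm(n_cpgs)
    w[w == 0] <- 1e-3
    y_range <- if (transform == "horvath") {
      forward_age_transform(age_range)
    } else {
      age_range
    }
    span <- diff(y_range)
    # scale so max per-CpG excursion stays inside [0, 1] around 0.5
    s <- 1.1 * span * max(abs(w)) / sum(w^2)
    w <- w * s
    intercept <- mean(y_range) - sum(w) / 2
    clock_definition(name = name, kind = kind, intercept = intercept,
                     coefficients = stats::setNames(w, cpgs),
                     transform = transform)
  })
}

# Cohort-wide planted shift vector.  Age-residualisation projects the
# estimate onto the orthocomplement of {1, age}, so a shift vector only
# survives it intact when it is orthogonal to both.  Construction: within
# each group the two central order statistics pin the median at the target
# while tail values (assigned in age-balanced ABBA order) carry the group
# mean offset; a minimal-norm correction on the tail values then makes the
# whole vector exactly orthogonal to {1, age}, keeping every tail value on
# its side of the group median.  At zero noise the downstream residual
# group medians therefore equal the planted targets exactly.
plant_shifts_cohort <- function(ages, group_idx, targets) {
  n <- length(ages)
  if (n == 0) return(numeric(0))
  t_bar <- sum(lengths(group_idx) * targets) / n
  offset <- -t_bar
  if (offset == 0 && all(targets == 0)) return(numeric(n))
  build <- function(extra_a) {
    sv <- numeric(n)
    tail_mask <- logical(n)
    side <- numeric(n)
    for (g in seq_along(group_idx)) {
      idx <- group_idx[[g]]
      ng <- length(idx)
      if (ng == 0) next
      tg <- targets[g]
      # small tail count: a wide central block at the target keeps the
      # noisy sample median tight around it (the median then averages
      # many near-target values instead of two order statistics)
      k <- max(1, min(floor((ng - 2) / 2), round(ng / 6)))
      if (ng < 4) k <- 0
      if (k == 0) {
        sv[idx] <- tg
        next
      }
      b <- offset * ng / k
      a <- abs(b) + 1 + extra_a
      ord <- idx[order(ages[idx])]
      sv[ord[(k + 1):(ng - k)]] <- tg
      tails <- ord[c(seq_len(k), (ng - k + 1):ng)]
      sgn <- rep(c(-1, 1, 1, -1), length.out = 2 * k)
      sv[tails] <- tg + ifelse(sgn < 0, -a, a + b)
      tail_mask[tails] <- TRUE
      side[tails] <- sgn
    }
    list(sv = sv, tail_mask = tail_mask, side = side)
  }
  extra <- 0
  sv_out <- NULL
  for (iter in 1:8) {
    bs <- build(extra)
    sv <- bs$sv
    idx_t <- which(bs$tail_mask)
    if (length(idx_t) >= 3) {
      B <- cbind(1, ages[idx_t])
      r <- c(sum(sv), sum(sv * ages))
      sv[idx_t] <- sv[idx_t] + drop(B %*% solve(crossprod(B), -r))
    }
    sv_out <- sv
    # verify tails did not cross the group median
    worst <- 0
    for (g in seq_along(group_idx)) {
      tl <- intersect(group_idx[[g]], idx_t)
      if (!length(tl)) next
      margin <- bs$side[tl] * (sv[tl] - targets[g])
      worst <- max(worst, -min(margin) + 1e-6)
    }
    if (worst <= 0) break
    extra <- extra + worst + 1
  }
  sv_out
}

#' Generate a beta matrix carrying age signal and planted shifts
#'
#' For each clock and sample, the target DNAm age is chronological age plus
#' a group shift whose within-group median equals the planted value for
#' that clock (and whose cohort-wide mean is zero, so the planted medians
#' survive age-residualisation).  Betas are constructed by inverting the
#' clock exactly -- distributing the required linear-predictor value across
#' the clock's CpGs -- then adding Normal noise and clipping to `[0, 1]`.
#' CpGs belonging to no clock are filled with Beta(2, 2) background.
#'
#' @param cohort A `sample_table` (see [gen_cohort()]).
#' @param clocks List of [clock_definition()] objects; clock names present
#'   in `spec$planted_accel_shifts` receive their planted shifts, others
#'   get zero shift.
#' @param spec The [cohort_spec()] used for the cohort (source of the
#'   planted shifts).
#' @param noise_sd Per-CpG Normal noise SD, beta units.
#' @param seed Integer RNG seed.
#' @param n_background Count of background CpGs shared by no clock.
#' @return Beta matrix (CpGs x samples).
#' @export
gen_betas <- function(cohort, clocks, spec = cohort_spec(), noise_sd = 0.01,
                      seed, n_background = 200) {
  validate_sample_table(cohort)
  if (length(clocks) == 0) stop_acl("need at least one clock")
  groups <- spec$group_names
  with_seed(seed, {
    blocks <- list()
    for (clock in clocks) {
      shifts <- spec$planted_accel_shifts[[clock$name]] %||% c(0, 0)
      group_idx <- lapply(groups, function(g) which(cohort$population == g))
      shift_vec <- plant_shifts_cohort(cohort$age, group_idx, shifts)
      target <- cohort$age + shift_vec
      y <- if (clock$transform == "horvath") {
        forward_age_transform(target, clock$adult_age)
      } else {
        target
      }
      w <- clock$coefficients
      u <- y - clock$intercept - sum(w) / 2
      b <- 0.5 + outer(w / sum(w^2), u)          # CpG x sample
      if (min(b) < -1e-9 || max(b) > 1 + 1e-9) {
        stop_acl(sprintf(
          paste0("clock '%s' cannot represent the planted targets within ",
                 "[0, 1] betas; rescale the clock (see gen_clock) or ",
                 "shrink the shifts"), clock$name))
      }
      colnames(b) <- cohort$sample_id
      blocks[[clock$name]] <- b
    }
    m <- do.call(rbind, blocks)
    if (n_background > 0) {
      bg <- matrix(stats::rbeta(n_background * nrow(cohort), 2, 2),
                   nrow = n_background,
                   dimnames = list(sprintf("bg%06d", seq_len(n_background)),
                                   cohort$sample_id))
      m <- rbind(m, bg)
    }
    if (noise_sd > 0) {
      m <- m + stats::rnorm(length(m), sd = noise_sd)
    }
    m <- pmin(pmax(m, 0), 1)
    # duplicated CpG ids across clocks are disambiguated by keeping first
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    validate_beta_matrix(m)
    m
  })
}

#' Generate the default clock set used by the study-design pipeline
#'
#' Four age clocks matching the calibration profile names (EEAA-, Hannum-,
#' Pheno- and Grim-type) plus one surrogate estimator.  The Hannum-type
#' clock uses 71 CpGs as a size convention.
#'
#' @param seed Integer RNG seed.
#' @return Named list of [clock_definition()] objects.
#' @export
gen_default_clocks <- function(seed) {
  specs <- list(
    list(name = "EEAA",           n = 71,  transform = "identity"),
    list(name = "AgeAccelHannum", n = 71,  transform = "identity"),
    list(name = "AgeAccelPheno",  n = 513, transform = "identity"),
    list(name = "AgeAccelGrim",   n = 120, transform = "identity"),
    list(name = "DNAmTIMP1",      n = 40,  transform = "identity",
         kind = "surrogate"))
  clocks <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    gen_clock(s$n, kind = s$kind %||% "age", transform = s$transform,
              seed = derive_seed(seed, i), name = s$name)
  })
  stats::setNames(clocks, vapply(clocks, `[[`, character(1), "name"))
}
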