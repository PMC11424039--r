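#' Effect specification for cohort simulation
#'
#' Programs the structure a synthetic developmental cohort's connectomes
#' carry: per-network baseline edge weight, a linear age slope (per year),
#' an additive sex offset (applied to males), an age-by-sex slope
#' difference, edge-level Gaussian noise, and a subject-level random
#' offset shared by all of a subject's edges. Between-network edges get a
#' common baseline with noise but no programmed effects.
#'
#' @param groups character vector of network names.
#' @param baseline per-group baseline edge weight (recycled), must be > 0.
#' @param age_slope per-group slope of edge weight per year of age
#'   (recycled).
#' @param sex_offset per-group additive male offset (recycled).
#' @param age_sex_slope per-group additional male age slope (recycled).
#' @param edge_sd edge-level noise SD.
#' @param subject_sd SD of the subject-level random offset.
#' @param between_baseline baseline for between-network edges.
#' @param edge_presence probability an edge is present at all (thinning;
#'   gives the connection-density covariate nonzero variance).
#' @param le_effect_nodes optional named list: group -> integer node
#'   indices whose incident within-group edges receive the age slope
#'   (default: all of the group's edges).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(groups,
                        baseline = 0.3,
                        age_slope = 0,
                        sex_offset = 0,
                        age_sex_slope = 0,
                        edge_sd = 0.05,
                        subject_sd = 0.02,
                        between_baseline = 0.15,
                        edge_presence = 0.85,
                        le_effect_nodes = NULL) {
  k <- length(groups)
  spec <- data.frame(
    group = groups,
    baseline = rep_len(baseline, k),
    age_slope = rep_len(age_slope, k),
    sex_offset = rep_len(sex_offset, k),
    age_sex_slope = rep_len(age_sex_slope, k)
  )
  if (any(spec$baseline <= 0)) stop_invalid("baselines must be positive")
  if (edge_sd < 0 || subject_sd < 0) stop_invalid("noise SDs must be nonnegative")
  if (edge_presence <= 0 || edge_presence > 1) {
    stop_invalid("edge_presence must be in (0, 1]")
  }
  structure(list(per_group = spec, edge_sd = edge_sd, subject_sd = subject_sd,
                 between_baseline = between_baseline,
                 edge_presence = edge_presence,
                 le_effect_nodes = le_effect_nodes),
            class = "effect_spec")
}

#' Simulate a developmental cohort of connectomes
#'
#' Generates `n` subject records emulating the cohort design the package's
#' statistical stage targets: ages uniform on `age_range`, `n_female`
#' females, lognormal intracranial volume mildly correlated with sex, and
#' a symmetric nonnegative connectome per subject whose within-network
#' edge weights follow
#' `w = baseline + slope * (age - age_min) + sex_offset * male +
#'  age_sex_slope * (age - age_min) * male + subject_offset + N(0, sd)`,
#' truncated at 0. Defaults mirror a cohort of 88 children aged 8-19
#' with 46 females.
#'
#' @param n number of subjects (>= 2).
#' @param assignment a `network_assignment` defining nodes and groups.
#' @param effects an [effect_spec()] over the assignment's groups.
#' @param age_range numeric length-2 age range in years.
#' @param n_female number of female subjects.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of subject records (class `subject_record`): `id`, `age`,
#'   `sex` (`"M"`/`"F"`), `icv` (mm^3), `connectome`.
#' @export
simulate_cohort <- function(n = 88, assignment, effects,
                            age_range = c(8, 19), n_female = 46, seed = 1) {
  if (n < 2) stop_invalid("n must be >= 2")
  if (n_female > n) stop_invalid("n_female cannot exceed n")
  map <- assignment_map(assignment)
  spec <- effects$per_group
  unknown <- setdiff(spec$group, unname(map))
  if (length(unknown) > 0) {
    stop_invalid("effect spec references unknown group(s): ",
                 paste(unknown, collapse = ", "))
  }
  nodes <- names(map)
  p <- length(nodes)
  ut <- which(upper.tri(matrix(0, p, p)))
  gi <- map[nodes[row(matrix(0, p, p))[ut]]]
  gj <- map[nodes[col(matrix(0, p, p))[ut]]]
  within <- gi == gj
  grow <- match(gi, spec$group)      # spec row per edge (within only)

  base_e <- ifelse(within, spec$baseline[grow], effects$between_baseline)
  slope_e <- ifelse(within, spec$age_slope[grow], 0)
  sexoff_e <- ifelse(within, spec$sex_offset[grow], 0)
  agesex_e <- ifelse(within, spec$age_sex_slope[grow], 0)
  base_e[is.na(base_e)] <- effects$between_baseline
  slope_e[is.na(slope_e)] <- 0; sexoff_e[is.na(sexoff_e)] <- 0
  agesex_e[is.na(agesex_e)] <- 0

  # restrict the age effect to edges incident to flagged nodes, if any
  if (!is.null(effects$le_effect_nodes)) {
    ri <- row(matrix(0, p, p))[ut]; ci <- col(matrix(0, p, p))[ut]
    for (g in names(effects$le_effect_nodes)) {
      gn <- which(unname(map) == g)
      flagged <- gn[effects$le_effect_nodes[[g]]]
      in_g <- within & gi == g
      touch <- (ri %in% flagged) | (ci %in% flagged)
      slope_e[in_g & !touch] <- 0
      agesex_e[in_g & !touch] <- 0
    }
  }

  with_seed(seed, {
    ages <- runif(n, age_range[1], age_range[2])
    sex <- rep("M", n)
    sex[sample.int(n, n_female)] <- "F"
    male <- as.numeric(sex == "M")
    # lognormal ICV, mild positive correlation with male sex
    icv <- exp(log(1.45e6) + 0.063 * male + rnorm(n, 0, 0.1))
    cohort <- vector("list", n)
    for (s in seq_len(n)) {
      a <- ages[s] - age_range[1]
      mu <- base_e + slope_e * a + sexoff_e * male[s] + agesex_e * a * male[s]
      subj_off <- rnorm(1, 0, effects$subject_sd)
      w <- mu + subj_off + rnorm(length(ut), 0, effects$edge_sd)
      if (effects$edge_presence < 1) {
        w[runif(length(ut)) > effects$edge_presence] <- 0
      }
      w <- pmax(0, w)
      m <- matrix(0, p, p, dimnames = list(nodes, nodes))
      m[ut] <- w
      m <- m + t(m)
      cohort[[s]] <- structure(
        list(id = sprintf("sub-%03d", s), age = ages[s], sex = sex[s],
             icv = icv[s],
             connectome = connectome(m, weighting = "IASF", groups = map)),
        class = "subject_record")
    }
    cohort
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat("Subject", x$id, "- age", round(x$age, 1), "sex", x$sex,
      "ICV", format(round(x$icv)), "mm^3\n")
  invisible(x)
}

#' Null cohort (no age or sex effects)
#'
#' [simulate_cohort()] with every age and sex effect set to zero and
#' positive noise SDs: the type-I-error harness for the statistical
#' stage.
#'
#' @inheritParams simulate_cohort
#' @param groups network names (default the eight canonical cortical
#'   networks).
#' @param nodes_per_group nodes per network.
#' @export
null_cohort <- function(n = 88, seed = 1, groups = canonical_networks(),
                        nodes_per_group = 4) {
  assign <- default_assignment(groups, nodes_per_group)
  eff <- effect_spec(groups)           # all effects at their zero defaults
  simulate_cohort(n, assign, eff, n_female = round(n * 46 / 88), seed = seed)
}

#' Eight canonical cortical network names
#' @return character vector of the canonical network names used as
#'   simulation defaults.
#' @export
canonical_networks <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "fronto_parietal", "default_mode", "subcortical")
}

#' Evenly-sized synthetic network assignment
#' @param groups group names.
#' @param nodes_per_group nodes per group.
#' @return a `network_assignment` with labelled nodes `n001, n002, ...`.
#' @export
default_assignment <- function(groups = canonical_networks(),
                               nodes_per_group = 4) {
  p <- length(groups) * nodes_per_group
  network_assignment(setNames(rep(groups, each = nodes_per_group),
                              sprintf("n%03d", seq_len(p))))
}

#' Serialize a cohort to a directory
#'
#' Writes one connectome CSV per subject plus `subjects.tsv`
#' (id, age, sex, icv).
#'
#' @param cohort list of subject records.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(id = s$id, age = s$age, sex = s$sex, icv = s$icv)
  }))
  utils::write.table(meta, file.path(dir, "subjects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in cohort) {
    write_connectome(s$connectome, file.path(dir, paste0(s$id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                            header = TRUE, colClasses = c(id = "character"))
  lapply(seq_len(nrow(meta)), function(i) {
    structure(list(
      id = meta$id[i], age = meta$age[i], sex = meta$sex[i], icv = meta$icv[i],
      connectome = read_connectome(file.path(dir, paste0(meta$id[i], ".csv")))
    ), class = "subject_record")
  })
}
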