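# Longitudinal protocol: inhibition groups, knowledge schedules, eight
# test phases, outcome classification and aggregation into the pooled
# solution-type table and per-phase trajectories.

#' Configuration of a simulated inhibition group
#'
#' Three low-knowledge groups (low, medium, high lateral inhibition, with
#' means 0.4, 0.6 and 0.8 and SD 0.1) are trained for 800 learning trials
#' and tested at phase t with the checkpoint after `100 t` trials.  The
#' high-knowledge group shares the high-inhibition distribution but is
#' trained for 1000 trials and tested at phase t with the checkpoint after
#' `100 t + 200` trials, modelling children who enter the study with more
#' advanced relational knowledge.
#'
#' @param name one of `"low"`, `"medium"`, `"high"`, `"high_knowledge"`.
#' @param n_sims simulated individuals in the group.
#' @return A list of class `dora_group` with fields `name`, `mu`, `sd`,
#'   `n_sims`, `n_phases`, `trials_per_phase`, `n_trials` and
#'   `checkpoint_offset`.
#' @export
group_config <- function(name = c("low", "medium", "high",
                                  "high_knowledge"),
                         n_sims = 100L) {
  name <- match.arg(name)
  mu <- c(low = 0.4, medium = 0.6, high = 0.8, high_knowledge = 0.8)[[name]]
  high_k <- name == "high_knowledge"
  structure(list(
    name = name, mu = mu, sd = 0.1, n_sims = as.integer(n_sims),
    n_phases = 8L, trials_per_phase = 20L,
    n_trials = if (high_k) 1000L else 800L,
    checkpoint_offset = if (high_k) 200L else 0L
  ), class = "dora_group")
}

#' Sample an individual's lateral-inhibition level
#'
#' Drawn from a normal distribution with the group's mean and SD 0.1,
#' clipped to the admissible range; the level is maturational — the same
#' value is used for an individual's learning and for all of its test
#' phases.
#'
#' @param group a [group_config()].
#' @param n number of draws.
#' @param config a [dora_config()] (supplies the clipping range).
#' @return Numeric vector of inhibition levels.
#' @export
sample_inhibition <- function(group, n = 1L, config = dora_config()) {
  x <- stats::rnorm(n, group$mu, group$sd)
  pmin(pmax(x, config$lambda_clip[1]), config$lambda_clip[2])
}

#' Run one inhibition group through the full longitudinal protocol
#'
#' For each simulated individual: draw an inhibition level once, generate
#' a fresh object world, run the relational-learning phase to the group's
#' horizon, then for each of the eight test phases load the scheduled
#' checkpoint, generate a fresh 20-item battery at the 30/35/35 difficulty
#' mix, and solve and classify every item.
#'
#' @param group a [group_config()].
#' @param seed integer seed; per-individual seeds are derived from it so
#'   any single simulation can be replayed.
#' @param config a [dora_config()].
#' @param progress print one line per simulated individual.
#' @return A data frame with one row per trial: `group`, `sim`, `seed`,
#'   `lambda`, `phase`, `checkpoint`, `item`, `difficulty`,
#'   `n_instances`, `n_correct`, `outcome`.
#' @export
run_group <- function(group, seed = 1L, config = dora_config(),
                      progress = FALSE) {
  stopifnot(inherits(group, "dora_group"))
  rows <- vector("list", group$n_sims)
  for (sim in seq_len(group$n_sims)) {
    sim_seed <- (seed + 7919L * sim) %% 2147483647L
    set.seed(sim_seed)
    lambda <- sample_inhibition(group, 1L, config)
    world <- generate_world()
    learning <- learn_relations(world, lambda, group$n_trials, config)
    recs <- vector("list", group$n_phases)
    for (phase in seq_len(group$n_phases)) {
      checkpoint <- 100L * phase + group$checkpoint_offset
      battery <- generate_battery(group$trials_per_phase,
                                  pool_size = world$pool_size)
      out <- lapply(seq_along(battery), function(item) {
        pb <- battery[[item]]
        ans <- solve_problem(pb, learning, checkpoint, lambda, config)
        cl <- classify_response(ans, pb)
        data.frame(group = group$name, sim = sim, seed = sim_seed,
                   lambda = lambda, phase = phase, checkpoint = checkpoint,
                   item = item, difficulty = pb$difficulty_class,
                   n_instances = cl$n_instances, n_correct = cl$n_correct,
                   outcome = as.character(cl$outcome),
                   stringsAsFactors = FALSE)
      })
      recs[[phase]] <- do.call(rbind, out)
    }
    rows[[sim]] <- do.call(rbind, recs)
    if (progress) {
      message(sprintf("  %s sim %d/%d (lambda = %.2f): %.0f%% analogical",
                      group$name, sim, group$n_sims, lambda,
                      100 * mean(rows[[sim]]$outcome == "analogical")))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate trial records into the solution-type table and trajectories
#'
#' @param records data frame of classified trials from [run_group()]
#'   (possibly several groups row-bound together).
#' @return An object of class `dora_experiment` with
#'   \describe{
#'     \item{summary_table}{percentage of analogical / incomplete /
#'       associative solutions per group, pooled over all phases and
#'       simulations.}
#'     \item{trajectories}{per-phase percentage of each outcome per
#'       group.}
#'     \item{by_difficulty}{percentage of analogical solutions per group
#'       and difficulty class.}
#'     \item{records}{the raw trial records.}
#'   }
#' @export
aggregate_results <- function(records) {
  if (!nrow(records)) stop("no trial records to aggregate")
  lv <- c("analogical", "incomplete", "associative")
  records$outcome <- factor(records$outcome, levels = lv)
  pct <- function(x) 100 * as.vector(table(x)) / length(x)
  groups <- unique(records$group)
  summary_table <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g,
               outcome = lv,
               percent = pct(records$outcome[records$group == g]),
               stringsAsFactors = FALSE)
  }))
  trajectories <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(sort(unique(records$phase)), function(ph) {
      sel <- records$group == g & records$phase == ph
      data.frame(group = g, phase = ph, outcome = lv,
                 percent = pct(records$outcome[sel]),
                 stringsAsFactors = FALSE)
    }))
  }))
  by_difficulty <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("easy", "medium", "hard"), function(d) {
      sel <- records$group == g & records$difficulty == d
      data.frame(group = g, difficulty = d,
                 percent_analogical =
                   100 * mean(records$outcome[sel] == "analogical"),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(summary_table = summary_table,
                 trajectories = trajectories,
                 by_difficulty = by_difficulty,
                 records = records),
            class = "dora_experiment")
}

#' Simulate the full longitudinal analogy experiment
#'
#' Runs every requested inhibition group through learning and the eight
#' test phases and aggregates the outcomes.  This is the package's main
#' entry point.
#'
#' @param groups group names (see [group_config()]).
#' @param n_sims simulated individuals per group.
#' @param seed integer master seed.
#' @param config a [dora_config()].
#' @param progress print per-individual progress lines.
#' @return A `dora_experiment` (see [aggregate_results()]).
#' @examples
#' \donttest{
#' ex <- simulate_trajectories(groups = c("low", "high"), n_sims = 2,
#'                             seed = 1)
#' summary(ex)
#' }
#' @export
simulate_trajectories <- function(groups = c("low", "medium", "high",
                                             "high_knowledge"),
                                  n_sims = 30L, seed = 1L,
                                  config = dora_config(),
                                  progress = FALSE) {
  records <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    g <- group_config(groups[gi], n_sims = n_sims)
    run_group(g, seed = seed + 1000L * (gi - 1L), config = config,
              progress = progress)
  }))
  aggregate_results(records)
}

#' @export
print.dora_experiment <- function(x, ...) {
  cat("Simulated analogy experiment:",
      length(unique(x$records$group)), "group(s),",
      length(unique(x$records$sim)), "simulation(s) per group,",
      nrow(x$records), "classified trials\n\n")
  cat("Solution types pooled over phases (%):\n")
  wide <- stats::reshape(x$summary_table, idvar = "outcome",
                         timevar = "group", direction = "wide")
  names(wide) <- sub("^percent\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.dora_experiment <- function(object, ...) {
  print(object)
  cat("\nAnalogical solutions by phase (%):\n")
  tr <- object$trajectories[object$trajectories$outcome == "analogical", ]
  wide <- stats::reshape(tr[, c("group", "phase", "percent")],
                         idvar = "phase", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^percent\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat("\nAnalogical solutions by difficulty (%):\n")
  print(object$by_difficulty, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.dora_experiment <- function(x, ...) {
  tr <- x$trajectories[x$trajectories$outcome == "analogical", ]
  groups <- unique(tr$group)
  phases <- sort(unique(tr$phase))
  mat <- sapply(groups, function(g) {
    tr$percent[tr$group == g][order(tr$phase[tr$group == g])]
  })
  graphics::matplot(phases, mat, type = "b", pch = 16, lty = 1,
                    col = seq_along(groups),
                    xlab = "test phase", ylab = "% analogical solutions",
                    ylim = c(0, 100), main = "Learning trajectories", ...)
  graphics::legend("bottomright", legend = groups,
                   col = seq_along(groups), lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Write experiment outputs as CSV files
#'
#' Writes `summary.csv` (group by solution-type percentages),
#' `trajectories.csv` (per-phase percentages), `difficulty.csv` and
#' `trials.csv` (raw classified trials) into a directory.
#'
#' @param x a `dora_experiment`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_csv <- function(x, dir) {
  stopifnot(inherits(x, "dora_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("summary.csv", "trajectories.csv",
                            "difficulty.csv", "trials.csv"))
  utils::write.csv(x$summary_table, paths[1], row.names = FALSE)
  utils::write.csv(x$trajectories, paths[2], row.names = FALSE)
  utils::write.csv(x$by_difficulty, paths[3], row.names = FALSE)
  utils::write.csv(x$records, paths[4], row.names = FALSE)
  invisible(paths)
}
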