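#' Synthetic multi-informant cohort generation
#'
#' Cohorts are generated from a latent-Normal threshold model: each child c has
#' a random intercept u_c ~ N(0, tau^2); each informant report of item j adds
#' noise e ~ N(0, sigma^2); the latent value is shifted by `delta` for planted
#' items in the ASD group and by linear age and gender effects; two ordered
#' cut-points map the latent value to the ordinal scores 0/1/2. Mothers and
#' fathers are present independently with configurable probabilities, with at
#' least one informant guaranteed per child.
#'
#' @name cohort
NULL

.DEFAULT_GROUPS <- c(
  ASD = 270, ADHD = 724, Anxiety = 203, PTSD = 91, Affective = 61,
  OCD = 56, Behavioral = 34, DisorderNOS = 52, OtherDSM = 69,
  NoClassification = 65, TD = 41
)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cohort generator configuration
#'
#' Default group sizes mirror the development sample's primary-classification
#' breakdown (ASD n=270, ADHD n=724, ..., typically developing n=41; 1666
#' children in total), father/mother presence probabilities its informant
#' counts, and the remaining parameters are the generator's own documented
#' choices.
#'
#' @param n_per_group Named integer vector of children per primary group; must
#'   include `ASD` plus at least one comparison group, all counts >= 1.
#' @param age_range Two numbers, years (default 6 to 18).
#' @param p_girl Probability a child is a girl.
#' @param mother_present_prob,father_present_prob Per-informant presence
#'   probabilities; a child whose two draws both fail keeps the mother.
#' @param item_ids Item IDs to simulate (default all 120).
#' @param planted_items Item IDs carrying the ASD latent shift.
#' @param delta Latent shift for planted items in the ASD group.
#' @param tau Child random-intercept SD (latent scale).
#' @param sigma Informant-level noise SD (latent scale).
#' @param thresholds Two strictly increasing latent cut-points for scores 1 and 2.
#' @param age_slope Latent change per year of (centered) age.
#' @param sex_shift Latent shift for girls.
#' @param seed Integer seed; identical configs and seeds give identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = .DEFAULT_GROUPS,
                          age_range = c(6, 18),
                          p_girl = 0.37,
                          mother_present_prob = 0.97,
                          father_present_prob = 0.78,
                          item_ids = 1:120,
                          planted_items = c(1, 5, 9, 17, 25, 38, 42, 48, 64,
                                            66, 69, 75, 80, 84, 111),
                          delta = 1.5,
                          tau = 0.5,
                          sigma = 1.0,
                          thresholds = c(0.5, 1.5),
                          age_slope = 0.02,
                          sex_shift = -0.1,
                          seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector of group sizes", call. = FALSE)
  }
  if (!"ASD" %in% names(n_per_group)) {
    stop("n_per_group must include an 'ASD' group", call. = FALSE)
  }
  if (any(n_per_group < 1)) {
    bad <- names(n_per_group)[n_per_group < 1]
    stop("every configured group needs at least one child; offending group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(n_per_group) < 2) {
    stop("need at least one comparison group besides ASD", call. = FALSE)
  }
  probs <- c(p_girl, mother_present_prob, father_present_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    stop("thresholds must be two strictly increasing cut-points", call. = FALSE)
  }
  if (tau < 0 || sigma <= 0) stop("need tau >= 0 and sigma > 0", call. = FALSE)
  item_ids <- sort(unique(as.integer(item_ids)))
  planted_items <- sort(unique(as.integer(planted_items)))
  if (!all(planted_items %in% item_ids)) {
    stop("planted_items must be a subset of item_ids", call. = FALSE)
  }
  structure(list(
    n_per_group = n_per_group, age_range = age_range, p_girl = p_girl,
    mother_present_prob = mother_present_prob,
    father_present_prob = father_present_prob,
    item_ids = item_ids, planted_items = planted_items, delta = delta,
    tau = tau, sigma = sigma, thresholds = thresholds,
    age_slope = age_slope, sex_shift = sex_shift, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a multi-informant ordinal cohort
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: list with `responses` (long data.frame:
#'   `child_id`, `informant` in mother/father, `item_id`, `score` 0/1/2),
#'   `children` (`child_id`, `age`, `gender` girl/boy, `group`, `subsample`
#'   clinical/TD), `planted_items`, and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- sum(config$n_per_group)
    group <- rep(names(config$n_per_group), times = config$n_per_group)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    gender <- ifelse(stats::runif(n) < config$p_girl, "girl", "boy")
    children <- data.frame(
      child_id = seq_len(n), age = age, gender = gender, group = group,
      subsample = ifelse(group == "TD", "TD", "clinical"),
      stringsAsFactors = FALSE
    )

    m <- length(config$item_ids)
    # child-level latent mean per item: planted shift + covariates + intercept
    shift <- outer(group == "ASD",
                   config$item_ids %in% config$planted_items) * config$delta
    covar <- config$age_slope * (age - mean(age)) +
      config$sex_shift * (gender == "girl")
    u <- stats::rnorm(n, 0, config$tau)
    mu <- shift + covar + u  # n x m via recycling down columns

    mother_present <- stats::runif(n) < config$mother_present_prob
    father_present <- stats::runif(n) < config$father_present_prob
    mother_present[!mother_present & !father_present] <- TRUE

    score_block <- function(present) {
      idx <- which(present)
      eps <- matrix(stats::rnorm(length(idx) * m, 0, config$sigma),
                    nrow = length(idx))
      lat <- mu[idx, , drop = FALSE] + eps
      sc <- (lat > config$thresholds[1]) + (lat > config$thresholds[2])
      data.frame(
        child_id = rep(idx, times = m),
        item_id = rep(config$item_ids, each = length(idx)),
        score = as.integer(sc),
        stringsAsFactors = FALSE
      )
    }
    mom <- score_block(mother_present); mom$informant <- "mother"
    dad <- score_block(father_present); dad$informant <- "father"
    responses <- rbind(mom, dad)
    responses <- responses[order(responses$child_id, responses$informant,
                                 responses$item_id),
                           c("child_id", "informant", "item_id", "score")]
    rownames(responses) <- NULL

    structure(list(responses = responses, children = children,
                   planted_items = config$planted_items, config = config),
              class = "cohort")
  })
}

#' @export
#' @method print cohort
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d children, %d response rows, %d items, %d planted>\n",
              nrow(x$children), nrow(x$responses),
              length(unique(x$responses$item_id)), length(x$planted_items)))
  invisible(x)
}

#' Generate a binary clinician-rating matrix
#'
#' Independent Bernoulli votes per clinician and item, emulating a panel asked
#' whether each item characterizes ASD (0/1).
#'
#' @param n_clinicians Number of raters (default 15).
#' @param p_vote Per-item vote probability: a single number, or a vector over
#'   `item_ids` (optionally named by item ID).
#' @param item_ids Item IDs rated (default all 120).
#' @param seed Integer seed.
#' @return Integer 0/1 matrix, `n_clinicians` x items, columns named by item ID.
#' @export
generate_clinician_ratings <- function(n_clinicians = 15, p_vote,
                                       item_ids = 1:120, seed = 1L) {
  item_ids <- as.integer(item_ids)
  if (length(p_vote) == 1L) p_vote <- rep(p_vote, length(item_ids))
  if (!is.null(names(p_vote))) {
    p_vote <- p_vote[as.character(item_ids)]
  }
  if (length(p_vote) != length(item_ids) || anyNA(p_vote) ||
      any(p_vote < 0 | p_vote > 1)) {
    stop("p_vote must give a probability in [0,1] for every item", call. = FALSE)
  }
  with_seed(seed, {
    votes <- matrix(
      stats::rbinom(n_clinicians * length(item_ids), 1L,
                    rep(p_vote, each = n_clinicians)),
      nrow = n_clinicians,
      dimnames = list(NULL, as.character(item_ids))
    )
    votes
  })
}

#' Write a cohort to disk
#'
#' Writes `responses.csv` (long format), `children.csv`, and `truth.json`
#' (planted items plus a config echo) under `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$children, file.path(dir, "children.csv"),
                   row.names = FALSE)
  truth <- list(planted_items = cohort$planted_items,
                config = unclass(cohort$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from disk, validating the schema
#'
#' Expects the layout written by [write_cohort()] (a `truth.json` sidecar is
#' optional for user-supplied data). Schema violations raise an error naming
#' the offending column.
#'
#' @param dir Directory holding `responses.csv` and `children.csv`.
#' @return A `cohort` object (with `planted_items = integer(0)` and
#'   `config = NULL` when no sidecar is present).
#' @export
read_cohort <- function(dir) {
  responses <- utils::read.csv(file.path(dir, "responses.csv"),
                               stringsAsFactors = FALSE)
  children <- utils::read.csv(file.path(dir, "children.csv"),
                              stringsAsFactors = FALSE)
  validate_cohort_tables(responses, children)
  truth_path <- file.path(dir, "truth.json")
  planted <- integer(0); config <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    planted <- as.integer(truth$planted_items)
    config <- truth$config
  }
  structure(list(responses = responses, children = children,
                 planted_items = planted, config = config),
            class = "cohort")
}

validate_cohort_tables <- function(responses, children) {
  need_r <- c("child_id", "informant", "item_id", "score")
  for (col in need_r) {
    if (!col %in% names(responses)) {
      stop("responses table is missing column '", col, "'", call. = FALSE)
    }
  }
  need_c <- c("child_id", "age", "gender", "group", "subsample")
  for (col in need_c) {
    if (!col %in% names(children)) {
      stop("children table is missing column '", col, "'", call. = FALSE)
    }
  }
  if (!all(responses$score %in% c(0L, 1L, 2L))) {
    stop("column 'score' must only contain 0, 1 or 2", call. = FALSE)
  }
  if (!all(responses$informant %in% c("mother", "father"))) {
    stop("column 'informant' must be 'mother' or 'father'", call. = FALSE)
  }
  key <- paste(responses$child_id, responses$informant, responses$item_id)
  if (anyDuplicated(key)) {
    stop("duplicate (child_id, informant, item_id) rows in responses",
         call. = FALSE)
  }
  if (!all(responses$child_id %in% children$child_id)) {
    stop("column 'child_id' in responses references children absent from the ",
         "children table", call. = FALSE)
  }
  invisible(TRUE)
}
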