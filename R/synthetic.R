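#' Demo fixture: the worked thyroid example
#'
#' Builds, through the regular fitting pipeline, the small thyroid subtree of
#' the worked example: transition probabilities 1, 0.333, 0.667, 0.5, 0.5 and
#' leaf class indicators 0, 0, 0, 1, 0, 1, together with the synthetic demo
#' patient (cytology TIR3B, female, age 48, no thyroiditis, no struma, nodule
#' 18 mm) and the default fuzzy configuration (age partition rising 40 to 50
#' years; nodule partition rising 10 to 20 mm; crisp cuts at 50 years and
#' 20 mm).
#'
#' On this fixture the membership-weighted traversal yields a positive-class
#' probability of 0.42672 (printed 0.427 to three decimals) while the crisp
#' traversal reaches a pure benign leaf (benign probability 1).
#'
#' @return A list with `model` (`fpt_model`), `tree`, `patient`
#'   ([patient_record()]), `config` (`fpt_config`) and `records` (the
#'   generating table).
#' @export
make_demo_fixture <- function() {
  config <- demo_config()
  block <- function(age, nodule, n0, n1) {
    n <- n0 + n1
    data.frame(class = "TIR3B", gender = "Female", age = age,
               thyroiditis = "No", struma = "No", nodule_mm = nodule,
               target = rep(c("0", "1"), c(n0, n1)), stringsAsFactors = FALSE)
  }
  records <- rbind(
    block(age = 45, nodule = 12, n0 = 100, n1 = 0),   # Under50, small -> benign
    block(age = 45, nodule = 25, n0 = 100, n1 = 0),   # Under50, large -> benign
    block(age = 55, nodule = 12, n0 = 333, n1 = 667), # 50Plus, small -> 0.333/0.667
    block(age = 55, nodule = 25, n0 = 500, n1 = 500)  # 50Plus, large -> 0.5/0.5
  )
  model <- fpt_fit(records, config)
  patient <- patient_record(
    statements = list(class = "TIR3B", gender = "Female",
                      thyroiditis = "No", struma = "No"),
    raw_values = c(age = 48, nodule_mm = 18)
  )
  list(model = model, tree = model$tree, patient = patient, config = config,
       records = records)
}

demo_config <- function() {
  fpt_config(
    feature_order = c("class", "gender", "age", "thyroiditis", "struma", "nodule_mm"),
    target = "target", positive_class = "1", negative_class = "0",
    variables = list(
      class = list(type = "categorical",
                   values = c("TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5")),
      gender = list(type = "binary", values = c("Female", "Male")),
      age = list(type = "fuzzy", universe = c(18, 95), units = "years",
                 crisp_threshold = 50,
                 sets = list(fuzzy_set("Under50", rbind(c(40, 1), c(50, 0))),
                             fuzzy_set("50Plus", rbind(c(40, 0), c(50, 1))))),
      thyroiditis = list(type = "binary", values = c("No", "Yes")),
      struma = list(type = "binary", values = c("No", "Yes")),
      nodule_mm = list(type = "fuzzy", universe = c(0, 80), units = "mm",
                       crisp_threshold = 20,
                       sets = list(fuzzy_set("SmallNodule", rbind(c(10, 1), c(20, 0))),
                                   fuzzy_set("LargeNodule", rbind(c(10, 0), c(20, 1)))))
    ),
    threshold = 0.5
  )
}

#' Cohort specifications for synthetic data
#'
#' Declares a feature schema (marginal distributions), a generating rule for
#' the binary outcome, and a target prevalence, from which
#' [generate_cohort()] draws reproducible synthetic cohorts. All shipped
#' schemas and distributions are invented stand-ins for undeposited clinical
#' data; they copy the published feature lists but none of the joint
#' distributions.
#'
#' @param features Named list; each entry has `type` in
#'   `c("categorical", "binary", "continuous")` plus, for discrete features,
#'   `values` and `probs` (marginals), and for continuous ones `dist`
#'   (`"uniform"` or `"normal"`), its parameters (`min`/`max` or
#'   `mean`/`sd`), and a clipping `universe`.
#' @param generating_rule Function mapping the drawn feature data.frame to a
#'   nonnegative relative risk per record. When `prevalence` is `NULL` the
#'   rule must return absolute probabilities in \[0, 1\].
#' @param prevalence Overall positive-class fraction the risks are rescaled
#'   to (in (0, 1)), or `NULL` to use the rule's values as-is.
#' @param n Default cohort size.
#' @param seed Default seed.
#' @param target Name of the outcome column (levels "0"/"1", positive "1").
#' @param config Optional matching [fpt_config()] carried along for fitting.
#' @return An object of class `fpt_cohort_spec`.
#' @export
cohort_spec <- function(features, generating_rule, prevalence = NULL,
                        n = 1000, seed = 1, target = "target", config = NULL) {
  if (!is.list(features) || is.null(names(features))) {
    fpt_stop("'features' must be a named list")
  }
  for (f in names(features)) {
    ft <- features[[f]]
    if (!ft$type %in% c("categorical", "binary", "continuous")) {
      fpt_stop("feature '%s': unknown type '%s'", f, ft$type %||% "<missing>")
    }
    if (ft$type %in% c("categorical", "binary")) {
      if (is.null(ft$values) || is.null(ft$probs) ||
          length(ft$values) != length(ft$probs)) {
        fpt_stop("feature '%s': 'values' and 'probs' must be declared and aligned", f)
      }
      if (abs(sum(ft$probs) - 1) > 1e-9 || any(ft$probs < 0)) {
        fpt_stop("feature '%s': 'probs' must be a probability vector", f)
      }
    } else {
      if (is.null(ft$dist) || !ft$dist %in% c("uniform", "normal")) {
        fpt_stop("feature '%s': continuous features need dist 'uniform' or 'normal'", f)
      }
      if (is.null(ft$universe) || length(ft$universe) != 2L) {
        fpt_stop("feature '%s': continuous features need a clipping universe", f)
      }
    }
  }
  if (!is.function(generating_rule)) fpt_stop("'generating_rule' must be a function")
  if (!is.null(prevalence) &&
      (!is_number(prevalence) || prevalence <= 0 || prevalence >= 1)) {
    fpt_stop("'prevalence' must lie strictly between 0 and 1")
  }
  structure(list(features = features, generating_rule = generating_rule,
                 prevalence = prevalence, n = n, seed = seed, target = target,
                 config = config),
            class = "fpt_cohort_spec")
}

#' Draw a synthetic cohort
#'
#' Records are drawn independently: discrete features from their declared
#' marginals, continuous features from their declared distribution clipped to
#' the universe, and the outcome from a Bernoulli draw with per-record
#' probability given by the generating rule (rescaled to hit the requested
#' prevalence in expectation). Fully reproducible from the seed.
#'
#' @param spec An [cohort_spec()].
#' @param n Cohort size (default from the spec).
#' @param seed Seed (default from the spec).
#' @return A data.frame with one column per feature plus the target column
#'   (levels "0"/"1").
#' @export
generate_cohort <- function(spec, n = spec$n, seed = spec$seed) {
  stopifnot(inherits(spec, "fpt_cohort_spec"))
  with_seed(seed, {
    cols <- lapply(spec$features, function(ft) {
      switch(ft$type,
        categorical = ,
        binary = sample(ft$values, n, replace = TRUE, prob = ft$probs),
        continuous = {
          x <- if (ft$dist == "uniform") {
            stats::runif(n, ft$min %||% ft$universe[1], ft$max %||% ft$universe[2])
          } else {
            stats::rnorm(n, ft$mean, ft$sd)
          }
          pmin(pmax(x, ft$universe[1]), ft$universe[2])
        })
    })
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    r <- spec$generating_rule(df)
    if (any(r < 0) || anyNA(r)) fpt_stop("generating_rule returned invalid risks")
    p <- if (is.null(spec$prevalence)) {
      if (any(r > 1)) fpt_stop("generating_rule must return probabilities when prevalence is NULL")
      r
    } else {
      scale_to_prevalence(r, spec$prevalence)
    }
    df[[spec$target]] <- as.character(stats::rbinom(n, 1, p))
    df
  })
}

# Rescale relative risks so the mean probability matches the prevalence,
# re-clipping to [0, 1] (a few fixed-point iterations absorb the clipping).
scale_to_prevalence <- function(r, prevalence) {
  if (mean(r) == 0) fpt_stop("generating_rule returned all-zero risks")
  p <- r
  for (i in 1:25) {
    p <- pmin(pmax(p * prevalence / mean(p), 0), 1)
    if (abs(mean(p) - prevalence) < 1e-12) break
  }
  p
}

#' Number of possible total realizations of a schema
#'
#' The product over the feature order of each feature's number of discrete
#' values (fuzzy variables contribute their number of linguistic terms).
#' Dividing the cohort size by this count gives the average number of records
#' per total realization, a sparsity diagnostic for the induced tree.
#'
#' @param config An `fpt_config` (with declared `values` for every discrete
#'   feature) or an `fpt_cohort_spec`.
#' @return Integer count of realizations.
#' @export
schema_realizations <- function(config) {
  if (inherits(config, "fpt_cohort_spec")) {
    if (is.null(config$config)) fpt_stop("cohort spec carries no model config")
    config <- config$config
  }
  stopifnot(inherits(config, "fpt_config"))
  sizes <- vapply(config$feature_order, function(f) {
    v <- config$variables[[f]]
    if (v$type == "fuzzy") return(length(v$linguistic$sets))
    if (is.null(v$values)) {
      fpt_stop("variable '%s': declare 'values' to count realizations", f)
    }
    length(v$values)
  }, numeric(1))
  as.integer(round(prod(sizes)))
}

# ---- shipped cohort templates ------------------------------------------

#' Synthetic thyroid-nodule cohort (invented distributions)
#'
#' Schema-faithful stand-in for the thyroid case study: a 5-level cytology
#' class (TIR2..TIR5), binary gender/thyroiditis/struma, continuous age
#' (years) and nodule dimension (mm), with a malignancy risk that grows with
#' cytology class, nodule size (through the large-nodule membership) and age.
#' The default size (401) mirrors the published cohort, and the default
#' prevalence 0.08 reflects that roughly 5 to 10% of thyroid nodules are
#' malignant. The schema admits 5 * 2^5 = 160 total realizations. All
#' marginals and the risk rule are invented.
#'
#' @param n Cohort size.
#' @param prevalence Positive fraction.
#' @param seed Seed.
#' @return An [cohort_spec()] carrying the matching model config.
#' @export
thyroid_cohort_spec <- function(n = 401, prevalence = 0.08, seed = 1) {
  large <- fuzzy_set("LargeNodule", rbind(c(10, 0), c(20, 1)))
  features <- list(
    class = list(type = "categorical",
                 values = c("TIR2", "TIR3A", "TIR3B", "TIR4", "TIR5"),
                 probs = c(0.40, 0.15, 0.20, 0.15, 0.10)),
    gender = list(type = "binary", values = c("Female", "Male"),
                  probs = c(0.78, 0.22)),
    age = list(type = "continuous", dist = "normal", mean = 55, sd = 14,
               universe = c(18, 95), units = "years"),
    thyroiditis = list(type = "binary", values = c("No", "Yes"), probs = c(0.8, 0.2)),
    struma = list(type = "binary", values = c("No", "Yes"), probs = c(0.75, 0.25)),
    nodule_mm = list(type = "continuous", dist = "normal", mean = 18, sd = 8,
                     universe = c(2, 60), units = "mm")
  )
  rule <- function(df) {
    base <- c(TIR2 = 0.2, TIR3A = 0.6, TIR3B = 1, TIR4 = 3, TIR5 = 8)[df$class]
    unname(base) * (1 + membership(large, df$nodule_mm)) * (1 + 0.3 * (df$age >= 50))
  }
  cohort_spec(features, rule, prevalence = prevalence, n = n, seed = seed,
              config = demo_config())
}

#' Synthetic chronic-kidney-disease cohort (invented distributions)
#'
#' Schema-faithful stand-in for the CKD case study: general patient
#' information (age, diabetes), blood values (serum creatinine, hemoglobin
#' for anemia, GFR stage), and urine values (proteinuria, phosphate), plus
#' potassium for hyperkalemia; the outcome is 2-year progression to end-stage
#' renal disease. Six variables carry two fuzzy sets each; the GFR stage is a
#' 4-level category, so the schema admits 4 * 2^7 = 512 total realizations.
#' The default size (2599) mirrors the published cohort. The fuzzy knots are
#' placeholders at clinically conventional cut regions and are meant to be
#' replaced by expert-supplied shapes; every distribution and the risk rule
#' are invented.
#'
#' @inheritParams thyroid_cohort_spec
#' @return An [cohort_spec()] carrying the matching model config.
#' @export
ckd_cohort_spec <- function(n = 2599, prevalence = 0.25, seed = 1) {
  ramps <- list(
    elderly = fuzzy_set("Elderly", rbind(c(55, 0), c(75, 1))),
    creat = fuzzy_set("HighCreatinine", rbind(c(1.5, 0), c(3.5, 1))),
    anemia = fuzzy_set("Anemia", rbind(c(10, 1), c(13, 0))),
    prot = fuzzy_set("HighProteinuria", rbind(c(0.3, 0), c(1.7, 1))),
    phos = fuzzy_set("HighPhosphate", rbind(c(3.5, 0), c(5.5, 1))),
    kal = fuzzy_set("Hyperkalemia", rbind(c(4.5, 0), c(5.5, 1)))
  )
  features <- list(
    age = list(type = "continuous", dist = "normal", mean = 66, sd = 12,
               universe = c(18, 95), units = "years"),
    diabetes = list(type = "binary", values = c("No", "Yes"), probs = c(0.6, 0.4)),
    creatinine = list(type = "continuous", dist = "normal", mean = 2.2, sd = 1.0,
                      universe = c(0.4, 10), units = "mg/dL"),
    hemoglobin = list(type = "continuous", dist = "normal", mean = 11.5, sd = 1.8,
                      universe = c(5, 18), units = "g/dL"),
    gfr_stage = list(type = "categorical", values = c("G3a", "G3b", "G4", "G5"),
                     probs = c(0.35, 0.30, 0.25, 0.10)),
    proteinuria = list(type = "continuous", dist = "normal", mean = 1.2, sd = 1.0,
                       universe = c(0, 12), units = "g/day"),
    phosphate = list(type = "continuous", dist = "normal", mean = 4.2, sd = 0.9,
                     universe = c(1, 10), units = "mg/dL"),
    potassium = list(type = "continuous", dist = "normal", mean = 4.6, sd = 0.6,
                     universe = c(2.5, 8), units = "mmol/L")
  )
  rule <- function(df) {
    base <- c(G3a = 0.25, G3b = 0.6, G4 = 2, G5 = 6)[df$gfr_stage]
    unname(base) *
      (1 + membership(ramps$creat, df$creatinine)) *
      (1 + 0.5 * membership(ramps$prot, df$proteinuria)) *
      (1 + 0.4 * (df$diabetes == "Yes")) *
      (1 + 0.3 * membership(ramps$anemia, df$hemoglobin)) *
      (1 + 0.2 * membership(ramps$phos, df$phosphate)) *
      (1 + 0.2 * membership(ramps$kal, df$potassium)) *
      (1 + 0.3 * membership(ramps$elderly, df$age))
  }
  config <- fpt_config(
    feature_order = c("age", "diabetes", "creatinine", "hemoglobin", "gfr_stage",
                      "proteinuria", "phosphate", "potassium"),
    target = "target", positive_class = "1", negative_class = "0",
    variables = list(
      age = list(type = "fuzzy", universe = c(18, 95), units = "years",
                 crisp_threshold = 65, sets = list(ramps$elderly)),
      diabetes = list(type = "binary", values = c("No", "Yes")),
      creatinine = list(type = "fuzzy", universe = c(0.4, 10), units = "mg/dL",
                        crisp_threshold = 2.5, sets = list(ramps$creat)),
      hemoglobin = list(type = "fuzzy", universe = c(5, 18), units = "g/dL",
                        crisp_threshold = 12, sets = list(ramps$anemia)),
      gfr_stage = list(type = "categorical", values = c("G3a", "G3b", "G4", "G5")),
      proteinuria = list(type = "fuzzy", universe = c(0, 12), units = "g/day",
                         crisp_threshold = 1, sets = list(ramps$prot)),
      phosphate = list(type = "fuzzy", universe = c(1, 10), units = "mg/dL",
                       crisp_threshold = 4.5, sets = list(ramps$phos)),
      potassium = list(type = "fuzzy", universe = c(2.5, 8), units = "mmol/L",
                       crisp_threshold = 5, sets = list(ramps$kal))
    ),
    threshold = 0.5
  )
  cohort_spec(features, rule, prevalence = prevalence, n = n, seed = seed,
              config = config)
}
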