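# shared fixtures: the default knowledge base, random case generators,
# and an independent hand-coded oracle for the target rules

kb_default <- load_default_kb()

rand_profile <- function() {
  patient_profile(
    sex = sample(c("male", "female"), 1),
    age = sample(18:90, 1),
    height = runif(1, 1.45, 1.95),
    weight = runif(1, 45, 120),
    has_diabetes = runif(1) < 0.2,
    has_chronic_renal_disease = runif(1) < 0.1
  )
}

rand_measurements <- function() {
  measurements(
    systolic_bp = sample(90:200, 1),
    diastolic_bp = 50,
    waist = runif(1, 60, 130),
    weight = runif(1, 45, 120),
    diet_behavior_score = sample(0:12, 1),
    bepsik_score = sample(5:25, 1) / 5,
    alcohol_per_day = sample(0:5, 1),
    alcohol_per_week = sample(0:25, 1),
    cigarettes_per_day = sample(0:30, 1),
    exercise_frequency = sample(0:7, 1),
    exercise_duration = sample(c(20, 45, 61, 90), 1),
    exercise_intensity = sample(1:3, 1)
  )
}

# Independent re-statement of the target rules (hand-coded, not read from
# the knowledge base) used as a brute-force oracle for engine statuses.
oracle_status <- function(item, prof, m) {
  on <- switch(item,
    blood_pressure = {
      target <- if (prof$age >= 60 && !prof$underlying_disease) 150 else 140
      m$systolic_bp < target
    },
    sodium_intake = m$diet_behavior_score < 5,
    body_weight = m$weight < 25 * prof$height^2,
    alcohol = {
      if (prof$sex == "male" && prof$weight >= 60)
        m$alcohol_per_day <= 2 && m$alcohol_per_week <= 14
      else
        m$alcohol_per_day <= 1 && m$alcohol_per_week <= 9
    },
    smoking = m$cigarettes_per_day < 1,
    stress = m$bepsik_score <= 1.6,
    waist_circumference = {
      target <- if (prof$sex == "male") 102 else 88
      m$waist < target
    },
    exercise = m$exercise_frequency > 4 && m$exercise_duration > 60 &&
      m$exercise_intensity > 2,
    stop("unknown item"))
  if (on) "on_target" else "off_target"
}

# full measurement set that meets every target for any profile
all_on_target_measurements <- function() {
  measurements(systolic_bp = 120, diastolic_bp = 70, waist = 80,
               weight = 50, diet_behavior_score = 0, bepsik_score = 1,
               alcohol_per_day = 0, alcohol_per_week = 0,
               cigarettes_per_day = 0, exercise_frequency = 5,
               exercise_duration = 70, exercise_intensity = "vigorous")
}

# brute-force two-sided signed-rank p-value: recompute the statistic from
# scratch for every sign pattern of the absolute differences
brute_force_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  a <- abs(d)
  r <- rank(a)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s > 0]))
  eps <- 1e-9
  min(1, 2 * min(mean(vs <= v_obs + eps), mean(vs >= v_obs - eps)))
}
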