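# The shipped 22-node ground-truth specification emulating an
# adolescent mental-health survey: 21 explanatory variables plus a
# binary NSSI outcome. Signed edges follow the hypothesized risk /
# protective pathways (protective effects carry negative weights into
# NSSI); tier assignments make gender, school grade and the four
# pandemic behavioral-change indicators exogenous. Discretization cut
# points were fixed once by quantile calibration of each node's latent
# scale at large n so that default marginals sit near the reference
# survey table (e.g. NSSI prevalence ~26%, depression ~35%).

cpcd_edge_table <- function() {
  # from, to, weight
  e <- rbind(
    c("Grade",               "Age",                 0.80),
    c("Grade",               "AcademicAnxiety",     0.25),
    c("Gender",              "Depression",          0.30),
    c("SSBChange",           "BMI",                 0.40),
    c("SSBChange",           "Depression",          0.30),
    c("SSBChange",           "NSSI",                0.35),
    c("ScreenChange",        "Depression",          0.40),
    c("ScreenChange",        "SleepDuration",      -0.30),
    c("SleepChange",         "SleepDuration",       0.60),
    c("PhysActChange",       "AcademicAnxiety",    -0.35),
    c("PhysActChange",       "PTSD",               -0.30),
    c("SleepDuration",       "AcademicAnxiety",    -0.30),
    c("SleepDuration",       "NSSI",               -0.25),
    c("CaregiverMentalHealth", "FamilyDysfunction", 0.50),
    c("FamilyDysfunction",   "AcademicAnxiety",     0.30),
    c("FamilyDysfunction",   "PTSD",                0.30),
    c("FamilyDysfunction",   "InternetAddiction",   0.30),
    c("FamilyDysfunction",   "LifeSatisfaction",   -0.50),
    c("FamilyDysfunction",   "Depression",          0.30),
    c("FamilyDysfunction",   "NSSI",                0.30),
    c("AcademicAnxiety",     "PTSD",                0.45),
    c("AcademicAnxiety",     "Depression",          0.40),
    c("AcademicAnxiety",     "AcademicPerformance",-0.40),
    c("AcademicAnxiety",     "Anxiety",             0.50),
    c("AcademicAnxiety",     "NSSI",                0.30),
    c("AcademicPerformance", "LifeSatisfaction",    0.30),
    c("SocialSupport",       "PYD",                 0.50),
    c("SocialSupport",       "Loneliness",         -0.50),
    c("Loneliness",          "Depression",          0.30),
    c("PYD",                 "InternetAddiction",  -0.35),
    c("PYD",                 "Depression",         -0.30),
    c("PYD",                 "LifeSatisfaction",    0.30),
    c("PYD",                 "NSSI",               -0.30),
    c("LifeSatisfaction",    "Depression",         -0.25),
    c("LifeSatisfaction",    "NSSI",               -0.30),
    c("PTSD",                "InternetAddiction",   0.40),
    c("PTSD",                "NSSI",                0.40),
    c("Depression",          "InternetAddiction",   0.35),
    c("Depression",          "Anxiety",             0.40),
    c("Depression",          "NSSI",                0.60),
    c("InternetAddiction",   "NSSI",                0.45))
  data.frame(from = e[, 1], to = e[, 2], weight = as.numeric(e[, 3]),
             stringsAsFactors = FALSE)
}

cpcd_node_table <- function() {
  list(
    Gender = list(tier = "exogenous_fixed", levels = c("male", "female")),
    Grade = list(tier = "exogenous_fixed", levels = as.character(1:8)),
    SleepChange = list(tier = "exogenous_covid", levels = c("-", "+")),
    PhysActChange = list(tier = "exogenous_covid", levels = c("-", "+")),
    ScreenChange = list(tier = "exogenous_covid", levels = c("-", "+")),
    SSBChange = list(tier = "exogenous_covid", levels = c("-", "+")),
    Age = list(tier = "endogenous", levels = NULL),
    BMI = list(tier = "endogenous", levels = c("normal", "overweight", "obesity")),
    SleepDuration = list(tier = "endogenous", levels = NULL),
    CaregiverMentalHealth = list(tier = "endogenous", levels = NULL),
    FamilyDysfunction = list(tier = "endogenous", levels = NULL),
    SocialSupport = list(tier = "endogenous", levels = NULL),
    Loneliness = list(tier = "endogenous", levels = NULL),
    PYD = list(tier = "endogenous", levels = NULL),
    AcademicAnxiety = list(tier = "endogenous", levels = as.character(1:5)),
    AcademicPerformance = list(tier = "endogenous", levels = NULL),
    PTSD = list(tier = "endogenous", levels = c("no", "yes")),
    LifeSatisfaction = list(tier = "endogenous", levels = NULL),
    Depression = list(tier = "endogenous", levels = c("no", "yes")),
    Anxiety = list(tier = "endogenous", levels = c("no", "yes")),
    InternetAddiction = list(tier = "endogenous",
                             levels = c("average", "occasional", "significant")),
    NSSI = list(tier = "endogenous", levels = c("no", "yes")))
}

# latent-scale cut points, fixed by one-off quantile calibration (see
# the methods vignette); exogenous nodes have standard-normal latents so
# their cut points are exact normal quantiles of the target marginals
cpcd_thresholds <- function() {
  list(
    Gender = stats::qnorm(0.5063),
    Grade = stats::qnorm(cumsum(c(0.0450, 0.0588, 0.1605, 0.1920,
                                  0.1251, 0.1285, 0.1521))),
    SleepChange = stats::qnorm(1 - 0.362),
    PhysActChange = stats::qnorm(1 - 0.4457),
    ScreenChange = stats::qnorm(1 - 0.355),
    SSBChange = stats::qnorm(1 - 0.2703),
    BMI = c(0.9126, 1.2605),
    AcademicAnxiety = c(-0.1409, 0.5564, 1.2257, 1.9262),
    PTSD = 1.2418,
    Depression = 1.7701,
    Anxiety = 2.4041,
    InternetAddiction = c(1.5186, 2.9602),
    NSSI = 2.1989)
}

#' The shipped CPCD-like ground-truth specification
#'
#' A fixed 22-node structural causal model emulating an adolescent
#' survey: exogenous gender and school grade, four exogenous binary
#' pandemic behavioral-change indicators (sleep, physical activity,
#' screen time, sugary-beverage consumption), endogenous psychological
#' and behavioral constructs, and a binary NSSI outcome with nine direct
#' parents. Risk edges carry positive weights, protective edges (PYD,
#' life satisfaction, sleep duration into NSSI) negative weights, all
#' with `|weight|` in `[0.25, 0.8]`.
#'
#' @return An [scm_spec].
#' @export
make_cpcd_like_spec <- function() {
  nodes <- cpcd_node_table()
  et <- cpcd_edge_table()
  g <- mixed_graph(names(nodes), kind = "dag")
  w <- numeric(0)
  for (i in seq_len(nrow(et))) {
    g <- add_directed_edge(g, et$from[i], et$to[i])
    w[paste0(et$from[i], "->", et$to[i])] <- et$weight[i]
  }
  th <- cpcd_thresholds()
  nm <- names(nodes)
  scm_spec(
    g, w,
    noise_sd = stats::setNames(ifelse(nm == "Age", 0.6, 1.0), nm),
    thresholds = th,
    tiers = stats::setNames(vapply(nodes, `[[`, character(1), "tier"), nm),
    levels = stats::setNames(lapply(nodes, `[[`, "levels"), nm))
}
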