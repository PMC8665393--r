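# MSAS-SF (Memorial Symptom Assessment Scale - Short Form) scoring.
#
# The instrument carries 32 symptom items: 28 physical symptoms rated for
# severity/distress on 0 (not present) .. 4 (very much), and 4
# psychological symptoms rated for frequency 1 (rarely) .. 4 (almost
# constantly), with 0 encoding "not present" so all items share one 0..4
# numeric range. Four summary scores are arithmetic means over fixed item
# subsets:
#   GDI    10 items: 4 psychological frequency items + 6 physical items
#   PHYS   12 physical items
#   PSYCH   6 items (the 4 frequency items + difficulty sleeping and
#           difficulty concentrating)
#   TMSAS  all 32 items

MSAS_PSYCH_FREQ <- c("sadness", "irritability", "nervousness", "anxiety")

MSAS_PHYSICAL <- c(
  "lack_of_appetite", "lack_of_energy", "drowsiness", "pain",
  "constipation", "dry_mouth", "nausea", "vomiting", "change_in_taste",
  "feeling_bloated", "dizziness", "weight_loss", "difficulty_sleeping",
  "difficulty_concentrating", "cough", "skin_changes",
  "numbness_tingling", "urination_problems", "shortness_of_breath",
  "diarrhea", "sweats", "mouth_sores", "sexual_interest_problems",
  "itching", "difficulty_swallowing", "hair_loss", "swelling_arms_legs",
  "not_look_like_myself")

MSAS_GDI_PHYS <- c("lack_of_appetite", "lack_of_energy", "drowsiness",
                   "pain", "constipation", "dry_mouth")
MSAS_PHYS_ITEMS <- c("lack_of_appetite", "pain", "constipation",
                     "lack_of_energy", "drowsiness", "nausea", "vomiting",
                     "dry_mouth", "change_in_taste", "feeling_bloated",
                     "dizziness", "weight_loss")
MSAS_PSYCH_ITEMS <- c("anxiety", "nervousness", "sadness",
                      "difficulty_sleeping", "difficulty_concentrating",
                      "irritability")

# Synonymous column headers accepted by the reader (normalized form ->
# canonical item name).
MSAS_ALIASES <- c(
  worrying = "anxiety",
  feeling_sad = "sadness",
  feeling_irritable = "irritability",
  feeling_nervous = "nervousness",
  feeling_drowsy = "drowsiness",
  change_in_the_way_food_tastes = "change_in_taste",
  problems_with_urination = "urination_problems",
  problems_with_sexual_interest_or_activity = "sexual_interest_problems",
  problems_with_sexual_interest = "sexual_interest_problems",
  numbness_tingling_in_hands_feet = "numbness_tingling",
  numbness_or_tingling_in_hands_feet = "numbness_tingling",
  changes_in_skin = "skin_changes",
  swelling_of_arms_or_legs = "swelling_arms_legs",
  i_don_t_look_like_myself = "not_look_like_myself",
  i_dont_look_like_myself = "not_look_like_myself",
  dont_look_like_myself = "not_look_like_myself")

#' MSAS-SF item catalog
#'
#' @return Data frame with one row per item: `item` (canonical snake-case
#'   name), `scale` (`physical` severity or `psychological` frequency) and
#'   logical membership columns `gdi`, `phys`, `psych`. All 32 items enter
#'   TMSAS.
#' @export
#' @examples
#' cat32 <- msas_catalog()
#' colSums(cat32[c("gdi", "phys", "psych")])  # 10, 12, 6
msas_catalog <- function() {
  item <- c(MSAS_PSYCH_FREQ, MSAS_PHYSICAL)
  data.frame(
    item = item,
    scale = rep(c("psychological", "physical"),
                c(length(MSAS_PSYCH_FREQ), length(MSAS_PHYSICAL))),
    gdi = item %in% c(MSAS_PSYCH_FREQ, MSAS_GDI_PHYS),
    phys = item %in% MSAS_PHYS_ITEMS,
    psych = item %in% MSAS_PSYCH_ITEMS,
    stringsAsFactors = FALSE)
}

msas_subscale_members <- function() {
  cat32 <- msas_catalog()
  list(gdi = cat32$item[cat32$gdi],
       phys = cat32$item[cat32$phys],
       psych = cat32$item[cat32$psych],
       tmsas = cat32$item)
}

normalize_item_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  ifelse(x %in% names(MSAS_ALIASES), unname(MSAS_ALIASES[x]), x)
}

#' Read an MSAS-SF response table
#'
#' Expects a CSV with a `patient_id` column plus one column per item.
#' Column headers are normalized to the canonical snake-case vocabulary
#' (synonyms such as `feeling_drowsy` map to `drowsiness`); empty fields
#' are missing responses. Items absent from the file are missing for all
#' patients.
#'
#' @param path CSV file path.
#' @return Data frame `patient_id` + 32 item columns in catalog order,
#'   integer values 0..4 or `NA`.
#' @export
read_msas <- function(path) {
  df <- read_table_checked(path, "patient_id")
  items <- msas_catalog()$item
  nm <- names(df)
  nm[nm != "patient_id"] <- normalize_item_name(nm[nm != "patient_id"])
  unknown <- setdiff(nm, c("patient_id", items))
  if (length(unknown))
    st_stop(path, ": unknown MSAS item column(s): ",
            paste(unknown, collapse = ", "), class = "steptrack_parse_error")
  names(df) <- nm
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)
  for (it in items) {
    v <- if (it %in% nm) parse_int(df[[it]]) else rep(NA_real_, nrow(df))
    if (any(is.nan(v)) || any(!is.na(v) & !(v %in% 0:4)))
      st_stop(path, ": item '", it, "' has a value outside 0..4",
              class = "steptrack_validation_error")
    out[[it]] <- as.integer(v)
  }
  if (anyDuplicated(out$patient_id))
    st_stop(path, ": duplicate patient_id", class = "steptrack_duplicate_error")
  out
}

#' Score the MSAS-SF subscales
#'
#' Each score is the arithmetic mean of its member items. A subscale is
#' prorated over the observed items when at least half of its members are
#' present; when more than half are missing the subscale is `NA` for that
#' patient. All scores lie in \[0, 4\]; lower is a lower symptom burden.
#'
#' @param responses Data frame as returned by [read_msas()]: `patient_id`
#'   plus item columns (missing columns are treated as all-missing items).
#' @return Data frame with columns `patient_id`, `gdi`, `phys`, `psych`,
#'   `tmsas` and the per-subscale item counts `n_gdi`, `n_phys`,
#'   `n_psych`, `n_tmsas` actually used.
#' @export
#' @examples
#' r <- data.frame(patient_id = "P1")
#' for (it in msas_catalog()$item) r[[it]] <- 0L
#' r$pain <- 4L
#' score_msas(r)$tmsas  # 4/32 = 0.125
score_msas <- function(responses) {
  stopifnot(is.data.frame(responses), "patient_id" %in% names(responses))
  members <- msas_subscale_members()
  items <- members$tmsas
  mat <- matrix(NA_real_, nrow = nrow(responses), ncol = length(items),
                dimnames = list(NULL, items))
  for (it in intersect(items, names(responses))) {
    v <- responses[[it]]
    if (any(!is.na(v) & !(v %in% 0:4)))
      st_stop("item '", it, "' has a value outside 0..4",
              class = "steptrack_validation_error")
    mat[, it] <- as.numeric(v)
  }
  out <- data.frame(patient_id = as.character(responses$patient_id),
                    stringsAsFactors = FALSE)
  for (sc in names(members)) {
    sub <- mat[, members[[sc]], drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    score <- ifelse(n_obs * 2 >= length(members[[sc]]),
                    rowMeans(sub, na.rm = TRUE), NA_real_)
    out[[sc]] <- score
    out[[paste0("n_", sc)]] <- as.integer(n_obs)
  }
  out
}

#' Pre/post improvement in MSAS-SF scores
#'
#' A subscale improves when the post-visit score is strictly lower than
#' the pre-visit score (lower score = lower burden). `delta` is
#' `pre - post`, so a positive delta is the magnitude of improvement.
#'
#' @param pre,post Score data frames from [score_msas()] for the baseline
#'   and C2D1 visits.
#' @param subscales Character subset of `c("gdi","phys","psych","tmsas")`.
#' @return Long data frame: `patient_id`, `subscale`, `pre`, `post`,
#'   `improved` (logical, `NA` when either score is missing), `delta`.
#' @export
msas_improvement <- function(pre, post,
                             subscales = c("gdi", "phys", "psych", "tmsas")) {
  subscales <- match.arg(subscales, several.ok = TRUE)
  ids <- intersect(pre$patient_id, post$patient_id)
  rows <- lapply(subscales, function(sc) {
    a <- pre[[sc]][match(ids, pre$patient_id)]
    b <- post[[sc]][match(ids, post$patient_id)]
    data.frame(patient_id = ids, subscale = sc, pre = a, post = b,
               improved = b < a, delta = a - b, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
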