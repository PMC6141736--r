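#' Validate a participant table
#'
#' Expected columns: `participant_id`, `age` (years), `gender` (1 = male,
#' 0 = female by default), and either `pss_total` (0-40) or item columns
#' `pss_1` ... `pss_10` (each 0-4), or both. When items are present the total
#' must equal their sum; if absent it is recomputed from the items.
#'
#' @param participants data.frame.
#' @param male_code,female_code values of the `gender` column denoting male
#'   and female; recoded to the canonical 1 = male, 0 = female.
#' @return data.frame of class `cni_participants`.
#' @export
validate_participants <- function(participants, male_code = 1, female_code = 0) {
  if (!is.data.frame(participants) ||
      !all(c("participant_id", "age", "gender") %in% names(participants)))
    mc_stop("participants must have columns participant_id, age, gender")
  if (nrow(participants) == 0L) mc_stop("empty participant table")
  p <- participants
  p$participant_id <- as.character(p$participant_id)
  if (anyDuplicated(p$participant_id))
    mc_stop("duplicate participant_id")
  p$age <- as.numeric(p$age)
  if (any(!is.finite(p$age)) || any(p$age < 0)) mc_stop("age must be a non-negative number")
  g <- p$gender
  gender <- ifelse(g == male_code, 1L, ifelse(g == female_code, 0L, NA_integer_))
  if (anyNA(gender)) mc_stop("gender values must match male_code or female_code")
  p$gender <- gender

  item_cols <- paste0("pss_", 1:10)
  has_items <- all(item_cols %in% names(p))
  if (has_items) {
    items <- as.matrix(p[, item_cols])
    storage.mode(items) <- "numeric"
    if (any(!is.finite(items)) || any(items < 0 | items > 4) || any(items != round(items)))
      mc_stop("PSS items must be integers in 0..4")
    tot <- as.integer(rowSums(items))
    if ("pss_total" %in% names(p) && any(as.numeric(p$pss_total) != tot))
      mc_stop("pss_total does not equal the sum of the PSS items")
    p$pss_total <- tot
  } else if ("pss_total" %in% names(p)) {
    p$pss_total <- as.numeric(p$pss_total)
    if (any(!is.finite(p$pss_total)) || any(p$pss_total < 0 | p$pss_total > 40))
      mc_stop("pss_total must lie in 0..40")
  } else {
    mc_stop("participants need either pss_total or pss_1..pss_10")
  }
  class(p) <- c("cni_participants", "data.frame")
  p
}

#' Read a participant table from CSV
#'
#' @inheritParams validate_participants
#' @param path CSV file.
#' @return data.frame of class `cni_participants`.
#' @export
read_participants <- function(path, male_code = 1, female_code = 0) {
  validate_participants(utils::read.csv(path, strip.white = TRUE),
                        male_code = male_code, female_code = female_code)
}

#' Assemble and validate a response dataset
#'
#' Joins long-format binary judgments to the battery and participant tables.
#' Every response must reference a known participant and item, responses are
#' strictly 0/1 (1 = the action was judged acceptable), and a
#' (participant, item) pair may occur at most once. Missing responses are
#' allowed but flagged: `complete` marks participants who answered all 24
#' items.
#'
#' @param battery a `cni_battery` (see [validate_battery()]).
#' @param participants a `cni_participants` (see [validate_participants()]).
#' @param responses data.frame with columns `participant_id`, `item_id`,
#'   `response`.
#' @return An object of class `cni_data`: a list with elements `battery`,
#'   `participants`, `responses` (with the item's cell joined on) and
#'   `complete` (named logical per participant).
#' @export
cni_data <- function(battery, participants, responses) {
  battery <- validate_battery(battery)
  if (!inherits(participants, "cni_participants"))
    participants <- validate_participants(participants)
  need <- c("participant_id", "item_id", "response")
  if (!is.data.frame(responses) || !all(need %in% names(responses)))
    mc_stop("responses must have columns participant_id, item_id, response")
  r <- responses[, need]
  r$participant_id <- as.character(r$participant_id)
  r$item_id <- as.character(r$item_id)
  r$response <- as.numeric(r$response)
  bad <- which(!(r$response %in% c(0, 1)))
  if (length(bad))
    mc_stop(sprintf("response not in {0,1} at row %d", bad[1]))
  orphan <- setdiff(r$participant_id, participants$participant_id)
  if (length(orphan))
    mc_stop(sprintf("responses reference unknown participant_id: %s",
                    paste(utils::head(orphan, 3), collapse = ", ")))
  orphan <- setdiff(r$item_id, battery$item_id)
  if (length(orphan))
    mc_stop(sprintf("responses reference unknown item_id: %s",
                    paste(utils::head(orphan, 3), collapse = ", ")))
  key <- paste(r$participant_id, r$item_id, sep = "\r")
  if (anyDuplicated(key))
    mc_stop(sprintf("duplicate response for (%s)",
                    sub("\r", ", ", key[duplicated(key)][1])))
  r$response <- as.integer(r$response)
  r$cell <- battery$cell[match(r$item_id, battery$item_id)]
  n_items <- table(factor(r$participant_id, participants$participant_id))
  complete <- as.vector(n_items) == nrow(battery)
  names(complete) <- participants$participant_id
  structure(list(battery = battery, participants = participants,
                 responses = r, complete = complete),
            class = "cni_data")
}

#' Read long-format responses from CSV
#'
#' @param path CSV with header `participant_id,item_id,response`.
#' @inheritParams cni_data
#' @return A `cni_data` object.
#' @export
read_responses <- function(path, battery, participants) {
  cni_data(battery, participants, utils::read.csv(path, strip.white = TRUE))
}

#' Write long-format responses to CSV
#'
#' @param data a `cni_data` object.
#' @param path output path.
#' @export
write_responses <- function(data, path) {
  stopifnot(inherits(data, "cni_data"))
  utils::write.csv(data$responses[, c("participant_id", "item_id", "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cni_data <- function(x, ...) {
  cat(sprintf("Moral-dilemma response dataset: %d participants x %d items, %d responses\n",
              nrow(x$participants), nrow(x$battery), nrow(x$responses)))
  cat(sprintf("Complete participants: %d of %d\n",
              sum(x$complete), length(x$complete)))
  invisible(x)
}
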