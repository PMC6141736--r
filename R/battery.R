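#' The default 24-item moral-dilemma battery
#'
#' Builds the standard battery layout: six base dilemmas, each presented in
#' four parallel forms crossing the moral norm (proscriptive, i.e. the norm
#' prohibits the action, vs. prescriptive, i.e. the norm prescribes it) with
#' the consequences of acting (benefits exceed costs vs. costs exceed
#' benefits). Dilemma texts are not modelled; items are identified by their
#' metadata labels only.
#'
#' @param base_dilemmas character vector of six base-dilemma labels.
#' @return A `data.frame` of class `cni_battery` with columns `item_id`,
#'   `base_dilemma`, `norm`, `consequences`.
#' @examples
#' b <- cni_battery()
#' table(b$norm, b$consequences)
#' @export
cni_battery <- function(base_dilemmas = c("transplant", "trolley", "vaccine",
                                          "abduction", "borders", "assisted_death")) {
  if (length(base_dilemmas) != 6L || anyDuplicated(base_dilemmas))
    mc_stop("'base_dilemmas' must be six distinct labels")
  grid <- expand.grid(base_dilemma = base_dilemmas,
                      norm = .norm_levels,
                      consequences = .cons_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$item_id <- paste(grid$base_dilemma,
                        ifelse(grid$norm == "proscriptive", "pro", "pre"),
                        ifelse(grid$consequences == "benefits_exceed_costs", "bgc", "bsc"),
                        sep = "_")
  validate_battery(grid[, c("item_id", "base_dilemma", "norm", "consequences")])
}

#' Validate a dilemma battery
#'
#' A valid battery contains exactly one item for every combination of six
#' base dilemmas, two norm types and two consequence types (24 items), so
#' that each of the four norm-by-consequences cells holds six items.
#'
#' @param battery data.frame with columns `item_id`, `base_dilemma`, `norm`,
#'   `consequences`.
#' @return The battery, normalised and classed `cni_battery`.
#' @export
validate_battery <- function(battery) {
  need <- c("item_id", "base_dilemma", "norm", "consequences")
  if (!is.data.frame(battery) || !all(need %in% names(battery)))
    mc_stop(paste("battery must have columns:", paste(need, collapse = ", ")))
  if (nrow(battery) == 0L) mc_stop("empty battery")
  battery <- battery[, need]
  for (col in need) battery[[col]] <- trimws(as.character(battery[[col]]))
  battery$norm <- tolower(battery$norm)
  battery$consequences <- tolower(battery$consequences)
  if (anyDuplicated(battery$item_id))
    mc_stop(sprintf("duplicate item_id: %s",
                    paste(unique(battery$item_id[duplicated(battery$item_id)]), collapse = ", ")))
  bad <- setdiff(unique(battery$norm), .norm_levels)
  if (length(bad)) mc_stop(sprintf("unknown norm value: %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(battery$consequences), .cons_levels)
  if (length(bad)) mc_stop(sprintf("unknown consequences value: %s", paste(bad, collapse = ", ")))

  counts <- table(factor(battery$norm, .norm_levels),
                  factor(battery$consequences, .cons_levels))
  off <- which(counts != 6L, arr.ind = TRUE)
  if (nrow(off)) {
    cellname <- paste0("(", rownames(counts)[off[1, 1]], ", ",
                       colnames(counts)[off[1, 2]], ")")
    mc_stop(sprintf("battery cell %s has %d items, expected 6",
                    cellname, counts[off[1, , drop = FALSE]]))
  }
  combos <- paste(battery$base_dilemma, battery$norm, battery$consequences)
  if (anyDuplicated(combos))
    mc_stop("battery has more than one item for some (base_dilemma, norm, consequences) combination")
  battery$cell <- cell_index(battery$norm, battery$consequences)
  rownames(battery) <- NULL
  class(battery) <- c("cni_battery", "data.frame")
  battery
}

#' Read a dilemma battery from CSV
#'
#' @param path CSV file with header `item_id,base_dilemma,norm,consequences`.
#'   Enum columns are parsed case-insensitively.
#' @return A validated `cni_battery`.
#' @export
read_battery <- function(path) {
  battery <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (nrow(battery) == 0L) mc_stop("empty battery")
  validate_battery(battery)
}

#' Write a dilemma battery to CSV
#'
#' @param battery a `cni_battery`.
#' @param path output path.
#' @export
write_battery <- function(battery, path) {
  battery <- validate_battery(battery)
  utils::write.csv(battery[, c("item_id", "base_dilemma", "norm", "consequences")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
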