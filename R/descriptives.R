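# Antenatal-care and delivery descriptives by outcome group: miscarriage,
# MTP, or pregnancy ongoing at 20 weeks.

OUTCOME_GROUPS <- c("MISCARRIAGE", "MTP", "ONGOING_20W")

#' Assign each pregnancy to an outcome group
#'
#' `MISCARRIAGE` / `MTP` for losses before 140 days (20 weeks);
#' `ONGOING_20W` for pregnancies that reached 140 days — stillbirths and
#' live births, whose delivery descriptors populate that column. MTPs at or
#' after 140 days default to the `MTP` group (set
#' `post20_mtp_group = "ONGOING_20W"` to count them as ongoing instead).
#' Records that fit no group (e.g. still ongoing at the data cut, or
#' missing the outcome gestational age) get `NA`.
#'
#' @param records Registry data frame.
#' @param post20_mtp_group Group for MTPs recorded at >= 140 days.
#' @return Character vector of group labels, `NA` where unassignable.
#' @export
assign_outcome_group <- function(records,
                                 post20_mtp_group = c("MTP", "ONGOING_20W")) {
  post20_mtp_group <- match.arg(post20_mtp_group)
  out <- records$outcome
  oga <- records$outcome_ga_days
  grp <- rep(NA_character_, nrow(records))
  early_loss <- !is.na(out) & out %in% LOSS_OUTCOMES & !is.na(oga) & oga < GA_20_WEEKS
  grp[early_loss] <- out[early_loss]
  reached_20w <- !is.na(out) & out %in% c("STILLBIRTH", "LIVEBIRTH")
  grp[reached_20w] <- "ONGOING_20W"
  late_mtp <- !is.na(out) & out == "MTP" & !is.na(oga) & oga >= GA_20_WEEKS
  grp[late_mtp] <- post20_mtp_group
  grp
}

#' Summarize antenatal and obstetric care by outcome group
#'
#' For each outcome group reports the group size, the percentage with at
#' least one antenatal-care (ANC) visit, and percentage breakdowns of ANC
#' visit bands (0 / 1--2 / >2), delivery or event attendant, and delivery
#' or event location, each to one decimal. Percentages are computed among
#' group members with the item recorded.
#'
#' @param records Registry data frame.
#' @param post20_mtp_group Passed to [assign_outcome_group()].
#' @return Data frame of class `outcome_group_summary` in long format:
#'   `group`, `block` (`"n"`, `"anc_any"`, `"anc_band"`, `"attendant"`,
#'   `"location"`), `level`, `value` (count for `"n"`, else percentage).
#' @export
summarize_groups <- function(records, post20_mtp_group = "MTP") {
  grp <- assign_outcome_group(records, post20_mtp_group)
  rows <- list()
  add <- function(group, block, level, value)
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, block = block, level = level, value = value,
      stringsAsFactors = FALSE)
  pct_block <- function(group, block, x, levels) {
    x <- x[!is.na(x)]
    n <- length(x)
    for (lv in levels)
      add(group, block, lv, if (n == 0) NA_real_ else round(100 * sum(x == lv) / n, 1))
  }
  for (g in OUTCOME_GROUPS) {
    sub <- records[!is.na(grp) & grp == g, , drop = FALSE]
    add(g, "n", "n", nrow(sub))
    anc <- sub$anc_visits[!is.na(sub$anc_visits)]
    add(g, "anc_any", ">=1 ANC visit",
        if (length(anc) == 0) NA_real_ else round(100 * mean(anc >= 1), 1))
    band <- ifelse(is.na(sub$anc_visits), NA_character_,
            ifelse(sub$anc_visits == 0, "0",
            ifelse(sub$anc_visits <= 2, "1-2", ">2")))
    pct_block(g, "anc_band", band, c("0", "1-2", ">2"))
    pct_block(g, "attendant", sub$attendant, ATTENDANT_LEVELS)
    pct_block(g, "location", sub$location, LOCATION_LEVELS)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_group_summary", "data.frame")
  out
}

#' @export
print.outcome_group_summary <- function(x, ...) {
  y <- as.data.frame(x)
  wide <- stats::reshape(y, idvar = c("block", "level"), timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
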