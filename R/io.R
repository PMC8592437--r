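# Serialization: trajectory CSV (one row per measurement) and patient
# records as JSON lines.

#' Write trajectories to CSV
#'
#' Columns: `patient_id, disease, variant, time_months, burden_pct,
#' censored` (0/1).
#'
#' @param trajs a single trajectory or a list of them.
#' @param path output file.
#' @export
write_trajectories <- function(trajs, path) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  df$censored <- as.integer(df$censored)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV written by [write_trajectories()].
#' @return list of trajectories, one per patient, in file order.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "disease", "variant", "time_months", "burden_pct",
            "censored")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
         function(d) new_trajectory(d$patient_id[1], d$disease[1],
                                    d$variant[1], d$time_months,
                                    d$burden_pct, as.logical(d$censored)))
}

#' Write patient records as JSON lines
#'
#' One JSON object per line: id, disease, parameters (named), schedule,
#' relapse label, excluded flag. The dense trajectory lives in the
#' trajectory CSV, not here.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path output file.
#' @export
write_records <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in cohort$records) {
    sch <- if (r$disease == "AML") {
      list(cycles_start = r$schedule$cycles[, 1],
           cycles_end = r$schedule$cycles[, 2])
    } else {
      list(t_stop = r$schedule$t_stop,
           half_dose_start = r$schedule$half_dose_start)
    }
    par_names <- if (r$disease == "AML") .AML_PAR_NAMES else .CML_PAR_NAMES
    obj <- list(id = r$id, disease = r$disease,
                params = r$params[par_names],
                free_names = r$params$free_names,
                schedule = sch, relapse = r$relapse, excluded = r$excluded)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read patient records from JSON lines
#'
#' Restores id, disease, parameters, schedule and label; the dense
#' trajectory must be re-attached from its CSV if needed.
#'
#' @param path file written by [write_records()].
#' @return list of patient records (without dense trajectories).
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    params <- if (o$disease == "AML") {
      do.call(aml_parameters, c(o$params, list(free_names = o$free_names)))
    } else {
      do.call(cml_parameters, c(o$params, list(free_names = o$free_names)))
    }
    schedule <- if (o$disease == "AML") {
      aml_schedule(cbind(o$schedule$cycles_start, o$schedule$cycles_end))
    } else {
      cml_schedule(o$schedule$t_stop, o$schedule$half_dose_start)
    }
    structure(list(id = o$id, disease = o$disease, params = params,
                   schedule = schedule, dense = NULL, relapse = o$relapse,
                   excluded = o$excluded),
              class = "patient_record")
  })
}
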