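#' Merge a fine parcellation into canonical networks (data-driven)
#'
#' Implements the overlap-based atlas merging rule: within each subject,
#' every ROI is assigned to the candidate network whose mask shares the
#' maximum number of voxels with the ROI mask. An ROI is retained only if
#' (a) its modal (most frequent) assignment across subjects holds in at
#' least `min_agreement` of them, and (b) its homologous (contralateral)
#' ROI, where one is defined, has the same modal assignment; otherwise the
#' ROI is discarded. An ROI overlapping no network in a subject counts as
#' disagreeing in that subject. Overlap-count ties within a subject go to
#' the smallest network id (deterministic).
#'
#' @param parcel_labels list (one per subject) of integer ROI label arrays.
#' @param network_labels list (one per subject) of integer network label
#'   arrays on the same grid as the subject's parcels.
#' @param homolog_map named integer vector mapping ROI label ->
#'   contralateral ROI label (symmetric where defined); ROIs without an
#'   entry skip the homology check.
#' @param min_agreement minimum fraction of subjects whose assignment must
#'   equal the modal assignment (default 0.8).
#' @param network_names optional named character vector network id -> name.
#' @return A `network_assignment`: list with `assignment` (data.frame:
#'   roi, group, agreement), `discarded` (data.frame: roi, reason), and
#'   `min_agreement`.
#' @export
merge_atlas <- function(parcel_labels, network_labels, homolog_map = NULL,
                        min_agreement = 0.8, network_names = NULL) {
  n_sub <- length(parcel_labels)
  if (n_sub == 0 || length(network_labels) != n_sub) {
    stop_invalid("need one parcel and one network label volume per subject")
  }
  rois <- sort(unique(unlist(lapply(parcel_labels, function(p) {
    setdiff(unique(as.integer(p)), 0L)
  }))))
  # per-subject winning network per ROI (NA = no overlap with any network)
  votes <- matrix(NA_integer_, length(rois), n_sub,
                  dimnames = list(rois, NULL))
  for (s in seq_len(n_sub)) {
    p <- as.integer(parcel_labels[[s]])
    w <- as.integer(network_labels[[s]])
    if (length(p) != length(w)) {
      stop_invalid("subject ", s, ": parcel and network volumes differ in size")
    }
    sel <- p > 0 & w > 0
    if (!any(sel)) next
    tab <- table(p[sel], w[sel])
    for (r in rownames(tab)) {
      cnt <- tab[r, ]
      if (sum(cnt) > 0) {
        votes[r, s] <- as.integer(colnames(tab)[which.max(cnt)])
      }
    }
  }
  modal <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    tt <- table(v)
    as.integer(names(tt)[which.max(tt)])
  })
  agreement <- vapply(seq_along(rois), function(i) {
    if (is.na(modal[i])) return(0)
    sum(votes[i, ] == modal[i], na.rm = TRUE) / n_sub
  }, numeric(1))
  names(modal) <- names(agreement) <- rois

  reason <- setNames(rep(NA_character_, length(rois)), rois)
  low <- agreement < min_agreement
  reason[low] <- "below_agreement"
  if (!is.null(homolog_map)) {
    for (r in as.character(rois)) {
      h <- homolog_map[r]
      if (is.na(reason[r]) && !is.na(h) && as.character(h) %in% names(modal)) {
        hc <- as.character(h)
        if (is.na(modal[hc]) || modal[r] != modal[hc]) {
          reason[r] <- "homolog_mismatch"
        }
      }
    }
  }
  retained <- is.na(reason)
  grp <- as.character(modal[retained])
  if (!is.null(network_names)) grp <- unname(network_names[grp])
  structure(list(
    assignment = data.frame(roi = as.character(rois[retained]), group = grp,
                            agreement = unname(agreement[retained])),
    discarded = data.frame(roi = as.character(rois[!retained]),
                           reason = unname(reason[!retained])),
    min_agreement = min_agreement
  ), class = "network_assignment")
}

#' Construct a network assignment directly
#'
#' For simulated cohorts and tests where the ROI -> network mapping is
#' known rather than derived from masks.
#'
#' @param map named vector: ROI label -> group name.
#' @return A `network_assignment`.
#' @export
network_assignment <- function(map) {
  structure(list(
    assignment = data.frame(roi = names(map), group = unname(map),
                            agreement = 1),
    discarded = data.frame(roi = character(0), reason = character(0)),
    min_agreement = 1
  ), class = "network_assignment")
}

#' @export
print.network_assignment <- function(x, ...) {
  cat("Network assignment:", nrow(x$assignment), "ROIs in",
      length(unique(x$assignment$group)), "groups;",
      nrow(x$discarded), "discarded\n")
  invisible(x)
}

#' @param x a `network_assignment`.
#' @param path TSV output path.
#' @rdname merge_atlas
#' @export
write_assignment <- function(x, path) {
  utils::write.table(x$assignment, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname merge_atlas
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(roi = "character"))
  structure(list(assignment = df,
                 discarded = data.frame(roi = character(0), reason = character(0)),
                 min_agreement = NA_real_),
            class = "network_assignment")
}
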