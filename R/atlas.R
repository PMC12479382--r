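#' The six analyzed resting-state networks
#'
#' Canonical labels in fixed order: visual (VIS), auditory-sensorimotor (ASM),
#' dorsal attention (DAN), salience (SAL), frontoparietal (FPN) and
#' default-mode (DMN). The limbic network (LIM) is excluded from analysis for
#' its low reproducibility and signal-to-noise ratio.
#' @export
ANALYZED_NETWORKS <- c("VIS", "ASM", "DAN", "SAL", "FPN", "DMN")

#' Parcel-to-network atlas
#'
#' Maps parcel ids to one of the six analyzed resting-state networks. Parcels
#' carrying any other label (typically LIM) are routed to an excluded list
#' with a warning and dropped from analysis.
#'
#' @param parcel_id Character vector of parcel identifiers.
#' @param network_label Character vector of network labels, same length.
#' @param analyzed_labels Labels treated as analyzed networks.
#'
#' @return An object of class `network_atlas` with elements `parcels`
#'   (data.frame of analyzed parcels), `networks` (label levels present) and
#'   `excluded` (data.frame of dropped parcels).
#' @export
network_atlas <- function(parcel_id, network_label,
                          analyzed_labels = ANALYZED_NETWORKS) {
  parcel_id <- as.character(parcel_id)
  network_label <- as.character(network_label)
  if (length(parcel_id) != length(network_label))
    stop("parcel_id and network_label lengths differ")
  if (anyDuplicated(parcel_id))
    stop("duplicate parcel id in atlas: ",
         parcel_id[duplicated(parcel_id)][1L])
  bad <- is.na(network_label) | network_label == ""
  if (any(bad))
    stop("parcel ", parcel_id[bad][1L], " has no network label")
  keep <- network_label %in% analyzed_labels
  if (any(!keep)) {
    dropped <- unique(network_label[!keep])
    warning("excluding ", sum(!keep), " parcel(s) with non-analyzed label(s): ",
            paste(dropped, collapse = ", "))
  }
  parcels <- data.frame(parcel_id = parcel_id[keep],
                        network = network_label[keep],
                        stringsAsFactors = FALSE)
  networks <- analyzed_labels[analyzed_labels %in% parcels$network]
  if (length(networks) == 0L)
    stop("atlas contains no analyzed parcels")
  empty <- setdiff(analyzed_labels, networks)
  # networks absent from the table are simply not present; an explicitly
  # empty analyzed network (label present for zero parcels) cannot occur here
  structure(
    list(parcels = parcels,
         networks = networks,
         excluded = data.frame(parcel_id = parcel_id[!keep],
                               network = network_label[!keep],
                               stringsAsFactors = FALSE)),
    class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat("<network_atlas> ", nrow(x$parcels), " analyzed parcels, ",
      length(x$networks), " networks\n", sep = "")
  print(table(factor(x$parcels$network, levels = x$networks)))
  if (nrow(x$excluded))
    cat("  excluded: ", nrow(x$excluded), " parcel(s) [",
        paste(unique(x$excluded$network), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# Parcel ids of one network, in atlas order; errors on unknown labels.
network_members <- function(atlas, network) {
  stopifnot(inherits(atlas, "network_atlas"))
  if (!network %in% atlas$networks)
    stop("unknown network label: ", network,
         " (known: ", paste(atlas$networks, collapse = ", "), ")")
  atlas$parcels$parcel_id[atlas$parcels$network == network]
}

# Column indices of a set of parcel ids within a scan, with validation.
parcel_index <- function(ts, parcel_id) {
  idx <- match(parcel_id, ts$parcel_ids)
  if (anyNA(idx))
    stop("parcel(s) not present in scan: ",
         paste(parcel_id[is.na(idx)], collapse = ", "))
  idx
}
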