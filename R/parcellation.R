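#' Parcellation objects
#'
#' A parcellation is the ordered table of brain structures that defines the
#' nodes of every connectivity matrix built against it: one row per region
#' with a positive integer label (0 is reserved for image background), a name,
#' a volume in cubic millimetres, a hub flag, and a community assignment.
#' The row order is the canonical node order.
#'
#' @param regions data.frame with columns `label_id`, `name`, `volume_mm3`,
#'   `is_hub`, `community`.
#' @return An object of class `parcellation` (a validated data.frame).
#' @export
parcellation <- function(regions) {
  stopifnot(is.data.frame(regions))
  needed <- c("label_id", "name", "volume_mm3", "is_hub", "community")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols) > 0) {
    stop("parcellation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  regions$label_id <- as.integer(regions$label_id)
  regions$name <- as.character(regions$name)
  regions$volume_mm3 <- as.double(regions$volume_mm3)
  regions$is_hub <- as.logical(regions$is_hub)
  if (anyDuplicated(regions$label_id)) stop("label_ids must be unique")
  if (any(regions$label_id <= 0L)) stop("label_ids must be positive (0 is background)")
  if (any(!is.finite(regions$volume_mm3)) || any(regions$volume_mm3 <= 0)) {
    stop("volumes must be strictly positive")
  }
  rownames(regions) <- NULL
  class(regions) <- c("parcellation", "data.frame")
  regions
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions, %d hub(s), %d communit%s\n",
              nrow(x), sum(x$is_hub), length(unique(x$community)),
              if (length(unique(x$community)) == 1) "y" else "ies"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more regions\n", nrow(x) - 6L))
  invisible(x)
}

hub_ids <- function(parc) parc$label_id[parc$is_hub]

#' Generate a synthetic parcellation with planted hubs
#'
#' Draws region volumes from a lognormal distribution and lays regions out in
#' three communities mimicking a gross brain plan: a left and a right
#' "hemisphere" block plus a "subcortical" block that contains all hubs.
#' Hubs receive the largest sampled volumes, scaled by `hub_multiplier`,
#' emulating large deep structures (a brainstem-like node) whose size and
#' connectivity dominate the network.
#'
#' @param n_regions number of regions (>= 3); labels are `1:n_regions`.
#' @param n_hubs number of hub regions (`0 <= n_hubs < n_regions`).
#' @param volume_spec list with `median` (mm^3), `sdlog` (lognormal
#'   dispersion), `hub_multiplier` (>= 1, scales hub volumes).
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return A [parcellation] object.
#' @export
make_parcellation <- function(n_regions, n_hubs = 1L,
                              volume_spec = list(median = 5000, sdlog = 0.5,
                                                 hub_multiplier = 3),
                              seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_hubs <- as.integer(n_hubs)
  if (is.na(n_regions) || n_regions < 3L) stop("n_regions must be >= 3")
  if (is.na(n_hubs) || n_hubs < 0L || n_hubs >= n_regions) {
    stop("need 0 <= n_hubs < n_regions")
  }
  med <- volume_spec$median %||% 5000
  sdlog <- volume_spec$sdlog %||% 0.5
  mult <- volume_spec$hub_multiplier %||% 3
  if (med <= 0 || sdlog < 0 || mult < 1) stop("invalid volume_spec")

  # subcortical block: all hubs plus ~1/5 of regions, capped so both
  # hemisphere blocks keep at least one region each
  n_sub <- max(n_hubs, round(n_regions / 5))
  n_sub <- min(n_sub, n_regions - 2L)
  n_sub <- max(n_sub, if (n_hubs > 0L) n_hubs else 1L)
  n_left <- ceiling((n_regions - n_sub) / 2)
  n_right <- n_regions - n_sub - n_left

  with_seed(seed, {
    vols <- sort(stats::rlnorm(n_regions, meanlog = log(med), sdlog = sdlog),
                 decreasing = TRUE)
    is_hub <- rep(FALSE, n_regions)
    community <- c(rep(3L, n_sub), rep(1L, n_left), rep(2L, n_right))
    if (n_hubs > 0L) {
      is_hub[seq_len(n_hubs)] <- TRUE
      vols[seq_len(n_hubs)] <- vols[seq_len(n_hubs)] * mult
    }
    name <- character(n_regions)
    name[is_hub] <- sprintf("Hub-%02d", seq_len(n_hubs))
    sub_other <- which(community == 3L & !is_hub)
    name[sub_other] <- sprintf("Subcortical-%02d", seq_along(sub_other))
    name[community == 1L] <- sprintf("Left-Cortex-%02d", seq_len(n_left))
    name[community == 2L] <- sprintf("Right-Cortex-%02d", seq_len(n_right))
    parcellation(data.frame(
      label_id = seq_len(n_regions), name = name, volume_mm3 = vols,
      is_hub = is_hub, community = community, stringsAsFactors = FALSE
    ))
  })
}

#' Read or write a parcellation table as CSV
#'
#' Columns: `label_id,name,volume_mm3,is_hub,community`.
#' @param parc a [parcellation].
#' @param path file path.
#' @export
write_parcellation_csv <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  utils::write.csv(as.data.frame(parc), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_parcellation_csv
#' @export
read_parcellation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parcellation(df)
}
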