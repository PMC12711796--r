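# Run configuration: YAML-backed, schema-validated, with documented
# defaults. The training hyperparameters of the reference experiments
# (input resolution 416, SGD lr 0.01, momentum 0.937, batch 8, 150
# epochs) are recorded for provenance even though this package contains
# no training loop.

config_defaults <- function() {
  list(variant = "baseline",
       num_classes = 5L,
       image_size = 416L,
       conf_threshold = 0.25,
       nms_iou = 0.45,
       grading = list(t_breaker = 0.05, t_half = 0.5,
                      t_commercial = 0.8, t_full = 0.9),
       seed = 0L,
       paths = list(images = NULL, labels = NULL, out = NULL),
       training = list(optimizer = "SGD", lr0 = 0.01, lrf = 0.01,
                       momentum = 0.937, batch_size = 8L, epochs = 150L,
                       mosaic = TRUE))
}

#' Load and validate a run configuration
#'
#' Unknown keys are rejected; threshold and size fields are range-checked.
#' An empty (or missing-key) file yields the documented defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `lbs_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- config_defaults()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      sub_bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(sub_bad))
        stop("unknown configuration keys: ",
             paste(paste0(nm, ".", sub_bad), collapse = ", "))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!cfg$variant %in% c("baseline", "test1", "test2", "test3", "test4", "full"))
    stop("invalid variant: ", cfg$variant)
  for (fld in c("conf_threshold", "nms_iou")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration field ", fld, " must lie in [0, 1], got ", v)
  }
  g <- cfg$grading
  if (!(g$t_breaker < g$t_half && g$t_half < g$t_commercial &&
        g$t_commercial < g$t_full && g$t_breaker > 0 && g$t_full < 1))
    stop("grading thresholds must be increasing inside (0, 1)")
  if (cfg$image_size %% 32L != 0L)
    stop("image_size must be divisible by 32")
  cfg$num_classes <- as.integer(cfg$num_classes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "lbs_config")
}

config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  # small rolling hash; enough to identify a configuration in logs
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

variant_from_config <- function(cfg)
  variant_spec(cfg$variant, num_classes = cfg$num_classes)
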