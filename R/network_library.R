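# Reference network rosters.
#
# The open-loop controller is a 7-neuron central-pattern-generator core:
# a primary inhibitory oscillator (I_dec / E_dec, mimicking the early-I and
# post-inspiratory populations), transition neurons (IE at the
# inspiration-expiration transition, EI at expiration-inspiration), tonic
# triggering neurons (I_decTON, EI_TON) and a tonic drive neuron ON that is
# excited by an external trigger while the system is switched on.
#
# The printed connectivity grid labels the IE neuron "Edec_TON" (it is the
# trigger of E_dec), E_dec "Edec_OUT", I_dec "Idec_OUT" and EI "EI_OUT";
# both naming schemes are accepted here, with the functional names used as
# canonical.
#
# The closed-loop roster adds three tonic sensor neurons (Vol_spk, C1_spk,
# C2_spk) whose spike trains encode lung volume and CO2 excess/deficit and
# whose connections into the core modulate depth and pace of the rhythm.

#' Printed-grid aliases for the core neurons
#'
#' Maps the connectivity-grid labels to the functional neuron names used in
#' this package.
#' @return Named character vector (alias -> canonical).
#' @export
roster_aliases <- function() {
  c(Edec_TON = "IE", Edec_OUT = "E_dec",
    Idec_TON = "I_decTON", Idec_OUT = "I_dec",
    EI_TON = "EI_TON", EI_OUT = "EI", ON = "ON")
}

canon_neuron <- function(x) {
  al <- roster_aliases()
  ifelse(x %in% names(al), unname(al[x]), x)
}

#' Construct a network roster
#'
#' @param name Roster label.
#' @param neurons Ordered character vector of neuron names.
#' @param connections data.frame with columns `pre`, `post`, `kinetic`
#'   (set index 1--5), `P` (signed strength, controller units) and
#'   `plastic_tag` (`"none"`, `"P_f"`, `"P_a"` or `"P_inj"`). Printed-grid
#'   neuron labels are translated to canonical names.
#' @param external_inputs Number of external (off-roster) input lines.
#' @return An object of class `network_roster`.
#' @export
network_roster <- function(name, neurons, connections, external_inputs = 0) {
  connections$pre <- canon_neuron(connections$pre)
  connections$post <- canon_neuron(connections$post)
  if (is.null(connections$plastic_tag)) connections$plastic_tag <- "none"
  stopifnot(
    all(connections$pre %in% neurons),
    all(connections$post %in% neurons),
    all(connections$plastic_tag %in% c("none", "P_f", "P_a", "P_inj"))
  )
  structure(
    list(name = name, neurons = neurons, connections = connections,
         external_inputs = external_inputs),
    class = "network_roster"
  )
}

#' @export
print.network_roster <- function(x, ...) {
  cat(sprintf("<network_roster '%s': %d neurons, %d connections, %d external input(s)>\n",
              x$name, length(x$neurons), nrow(x$connections), x$external_inputs))
  invisible(x)
}

#' Build the reference open-loop controller roster
#'
#' The 7-neuron rhythm-generating core with its 16 printed connection
#' strengths, plus one external trigger line onto the tonic ON neuron. The
#' optional follower extension adds the I_inc premotor neuron (triggered by
#' EI, inhibited by E_dec, self-excited) whose windowed spike count is the
#' stimulation ratio; its strengths are not printed in the source grid and
#' ship as package calibration values.
#'
#' @param include_follower Add the I_inc follower neuron and its wiring
#'   (default FALSE: the bare 7-neuron core used for the connectivity
#'   accounting).
#' @param follower Named list of the three follower strengths
#'   (`EI_to_Iinc`, `Edec_to_Iinc`, `Iinc_self`); calibration values, not
#'   from the printed grid. The expiratory inhibition uses the slowest
#'   kinetics so the follower stays silent through expiration, and the
#'   self-excitation is kept below the self-sustaining level so the burst
#'   cannot latch.
#' @return A [network_roster()].
#' @export
build_open_loop <- function(include_follower = FALSE,
                            follower = list(EI_to_Iinc = 1280,
                                            Edec_to_Iinc = -1500,
                                            Iinc_self = 80)) {
  conn <- data.frame(
    pre = c("IE", "IE", "E_dec", "E_dec", "E_dec", "E_dec",
            "I_decTON", "I_decTON", "I_dec", "I_dec", "I_dec",
            "EI_TON", "EI_TON", "EI", "EI", "ON"),
    post = c("IE", "E_dec", "IE", "I_dec", "EI_TON", "EI",
             "I_decTON", "I_dec", "E_dec", "I_decTON", "EI",
             "EI_TON", "EI", "I_decTON", "EI_TON", "IE"),
    kinetic = c(3L, 1L, 1L, 4L, 4L, 4L,
                3L, 4L, 1L, 3L, 4L,
                3L, 2L, 2L, 2L, 4L),
    P = c(600, 5000, -2200, -250, 8000, -500,
          40, 500, -1500, -5000, -350,
          40, 400, 200, 1280, 1280),
    plastic_tag = "none",
    stringsAsFactors = FALSE
  )
  conn$plastic_tag[conn$pre == "IE" & conn$post == "E_dec"] <- "P_f"
  neurons <- c("I_dec", "I_decTON", "IE", "E_dec", "EI_TON", "EI", "ON")
  if (include_follower) {
    neurons <- c(neurons, "I_inc")
    fol <- data.frame(
      pre = c("EI", "E_dec", "I_inc"),
      post = c("I_inc", "I_inc", "I_inc"),
      kinetic = c(2L, 2L, 3L),
      P = c(follower$EI_to_Iinc, follower$Edec_to_Iinc, follower$Iinc_self),
      plastic_tag = c("none", "none", "P_a"),
      stringsAsFactors = FALSE
    )
    conn <- rbind(conn, fol)
  }
  network_roster(
    name = if (include_follower) "open_loop+follower" else "open_loop",
    neurons = neurons, connections = conn, external_inputs = 1
  )
}

#' Build the reference closed-loop controller roster
#'
#' Extends an open-loop roster with the three tonic sensor neurons: Vol_spk
#' (volume-encoded; triggers the rhythm in place of the external ON line),
#' C1_spk (active when CO2 exceeds baseline; pushes the rhythm faster and
#' deeper) and C2_spk (active when CO2 is below baseline; slows the rhythm).
#' Their connection strengths into the core are not printed in the source
#' material and ship as package calibration values; strengths carrying the
#' `P_inj` tag are overridden per scenario, and `P_f`/`P_a`-tagged
#' connections are adapted on-line by the plasticity rule.
#'
#' @param open_loop An open-loop roster from [build_open_loop()].
#' @param tonic Named list of sensor-neuron strengths (calibration values).
#'   Vol_spk triggers the inspiration-expiration transition at high lung
#'   volume and suppresses inspiratory onset while the lung is inflated (an
#'   inflation-reflex-like action); C1_spk (CO2 excess) shortens expiration
#'   and deepens inspiration; C2_spk (CO2 deficit) lengthens expiration.
#' @return A [network_roster()] with 3 external sensor input lines.
#' @export
build_closed_loop <- function(open_loop = build_open_loop(),
                              tonic = list(Vol_to_IE = 1280,
                                           Vol_to_IdecTON = -300,
                                           Vol_to_Idec = -250,
                                           C1_to_Edec = -200,
                                           C1_to_Idec = 100,
                                           C1_to_EITON = 100,
                                           C2_to_Edec = 100,
                                           C2_to_EI = -100,
                                           Vol_to_Iinc = 800)) {
  neurons <- c(open_loop$neurons, "Vol_spk", "C1_spk", "C2_spk")
  add <- data.frame(
    pre = c("Vol_spk", "Vol_spk", "Vol_spk",
            "C1_spk", "C1_spk", "C1_spk",
            "C2_spk", "C2_spk"),
    post = c("IE", "I_decTON", "I_dec",
             "E_dec", "I_dec", "EI_TON",
             "E_dec", "EI"),
    kinetic = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 4L),
    P = c(tonic$Vol_to_IE, tonic$Vol_to_IdecTON, tonic$Vol_to_Idec,
          tonic$C1_to_Edec, tonic$C1_to_Idec, tonic$C1_to_EITON,
          tonic$C2_to_Edec, tonic$C2_to_EI),
    plastic_tag = c("none", "none", "none",
                    "none", "P_inj", "none",
                    "none", "none"),
    stringsAsFactors = FALSE
  )
  # follower variant: the closed-loop trigger line, volume-gated so the
  # stimulation amplifies the native inspiratory effort in phase and falls
  # silent below the gating volume (the amplitude node, adapted on-line)
  if ("I_inc" %in% open_loop$neurons) {
    add <- rbind(add, data.frame(
      pre = "Vol_spk", post = "I_inc", kinetic = 4L,
      P = tonic$Vol_to_Iinc, plastic_tag = "P_inj",
      stringsAsFactors = FALSE
    ))
  }
  conn <- rbind(open_loop$connections, add)
  network_roster(
    name = paste0("closed_loop", if (grepl("follower", open_loop$name)) "+follower" else ""),
    neurons = neurons, connections = conn,
    external_inputs = 3  # the three sensor feeds
  )
}

#' Remove the tonic sensor neurons from a closed-loop roster
#'
#' Inverse of [build_closed_loop()]: drops Vol_spk, C1_spk, C2_spk and every
#' connection touching them, restoring the open-loop wiring.
#'
#' @param roster A closed-loop roster.
#' @return The open-loop [network_roster()].
#' @export
strip_tonic_sensors <- function(roster) {
  tonic <- c("Vol_spk", "C1_spk", "C2_spk")
  keep_n <- setdiff(roster$neurons, tonic)
  conn <- roster$connections
  conn <- conn[!(conn$pre %in% tonic) & !(conn$post %in% tonic), , drop = FALSE]
  rownames(conn) <- NULL
  network_roster(name = "open_loop", neurons = keep_n, connections = conn,
                 external_inputs = 1)
}

#' Connectivity-density statistics of a roster
#'
#' For C connections among N neurons with maximum observed fan-in MaxC:
#' all-to-all density `100*C/N^2`, MaxC-to-all density `100*C/(N*MaxC)`,
#' 8-to-all density `100*C/(8*N)` (the hardware fan-in budget), and the
#' connections-per-neuron ratio `C/N`.
#'
#' @param roster A [network_roster()], or NULL when `C`, `N`, `MaxC` are
#'   given directly.
#' @param include_external Count the roster's external input lines in C
#'   (the convention under which the open-loop core is 16 + 1 = 17
#'   connections).
#' @param C,N,MaxC Direct counts (override the roster).
#' @param max_fan_in The fan-in budget used for the "8-to-all" figure.
#' @return List with `C`, `N`, `MaxC`, `all_to_all`, `maxc_to_all`,
#'   `eight_to_all` (percent) and `c_per_n`.
#' @export
connectivity_stats <- function(roster = NULL, include_external = FALSE,
                               C = NULL, N = NULL, MaxC = NULL,
                               max_fan_in = 8) {
  if (!is.null(roster)) {
    if (is.null(N)) N <- length(roster$neurons)
    if (is.null(C)) {
      C <- nrow(roster$connections) +
        if (include_external) roster$external_inputs else 0
    }
    if (is.null(MaxC)) {
      fan_in <- table(factor(roster$connections$post, levels = roster$neurons))
      MaxC <- max(as.integer(fan_in), if (include_external) 1L else 0L)
    }
  }
  stopifnot(!is.null(C), !is.null(N), !is.null(MaxC))
  if (N == 0) stop("connectivity_stats: empty roster (N = 0)")
  list(
    C = C, N = N, MaxC = MaxC,
    all_to_all = 100 * C / N^2,
    maxc_to_all = if (MaxC > 0) 100 * C / (N * MaxC) else 0,
    eight_to_all = 100 * C / (max_fan_in * N),
    c_per_n = C / N
  )
}

#' Serialize a roster to a YAML network config
#'
#' @param roster A [network_roster()].
#' @param path File path; the config has sections `name`, `neurons`,
#'   `connections`, `external_inputs`.
#' @export
write_roster_yaml <- function(roster, path) {
  obj <- list(
    name = roster$name,
    neurons = as.list(roster$neurons),
    external_inputs = roster$external_inputs,
    connections = lapply(seq_len(nrow(roster$connections)), function(i) {
      as.list(roster$connections[i, c("pre", "post", "kinetic", "P", "plastic_tag")])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a roster from a YAML network config
#'
#' @param path File written by [write_roster_yaml()] (or hand-authored with
#'   the same schema).
#' @return A [network_roster()].
#' @export
read_roster_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  conn <- do.call(rbind, lapply(obj$connections, function(cn) {
    data.frame(pre = cn$pre, post = cn$post, kinetic = as.integer(cn$kinetic),
               P = as.numeric(cn$P), plastic_tag = cn$plastic_tag,
               stringsAsFactors = FALSE)
  }))
  network_roster(obj$name, unlist(obj$neurons), conn,
                 external_inputs = obj$external_inputs %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
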