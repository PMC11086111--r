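#!/usr/bin/env Rscript

# Stage 2: landmarks -> postural parameters.
#
# Reads the landmark captures produced by stage 1, validates them, and
# computes the 22 postural parameters per subject and session (joint
# angles fused across the coronal views by circular mean; neck/trunk from
# the lateral view). Writes results/profiles.csv.

suppressMessages(library(posturekit))

metadata <- utils::read.csv("results/cohort/metadata.csv", stringsAsFactors = FALSE)
cohort_data <- read_captures("results/cohort/captures.csv", metadata = metadata)
cat(sprintf("read %d subjects\n", length(cohort_data$subjects)))

# validation pass: count findings instead of failing
n_findings <- sum(vapply(cohort_data$subjects, function(s) {
  sum(vapply(s$captures, function(cp) nrow(validate_capture(cp)), 0L))
}, 0L))
cat(sprintf("capture validation findings: %d\n", n_findings))

profiles <- profile_cohort(cohort_data)
write_profiles(profiles, "results/profiles.csv")
cat(sprintf(
  "wrote %d profile rows (%d session-2) to results/profiles.csv\n",
  nrow(profiles), sum(profiles$session == 2)
))

means <- colMeans(profiles[profiles$session == 1, posture_parameters()])
cat("session-1 parameter means:\n")
print(round(means, 2))
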