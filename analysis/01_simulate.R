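#!/usr/bin/env Rscript
# Generate the synthetic multimodal study: 21 participants x 4 clips
# (58/35/21/55 s) at 256 Hz, with fixed emotion-condition counts
# 9 relaxed / 22 sad / 40 happy / 13 angry. Writes the session manifest
# (conditions, SAM ratings, true generative parameters, seeds) and one
# example session CSV.

library(affectfuse)

seed <- 20260921
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- synth_config(master_seed = seed)
ds <- generate_dataset(cfg)

cat("Generated", length(ds$recordings), "sessions\n")
print(table(factor(ds$manifest$emotion, emotion_levels())))

# every generated SAM rating must fall in its own condition's quadrant
stopifnot(all(as.character(label_emotion(ds$manifest$valence,
                                         ds$manifest$arousal)) ==
              ds$manifest$emotion))
cat("All SAM ratings are quadrant-consistent with their conditions\n")

write.csv(ds$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
write_session_csv(ds$recordings[[1]],
                  file.path(out, "example_session_p1_c1.csv"))
cat("Wrote", file.path(out, "manifest.csv"), "and an example session CSV\n")
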