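# Internal engine entry points exercised directly by the model tests.
nn_forward_for_test <- denseunet:::nn_forward
nn_backward_for_test <- denseunet:::nn_backward
adam_init_for_test <- denseunet:::adam_init
adam_step_for_test <- function(net, pg, st, lr) denseunet:::adam_step(net, pg, st, lr = lr)
combined_loss_grad_for_test <- denseunet:::combined_loss_grad
derive_seeds <- denseunet:::derive_seeds
with_seed_for_test <- denseunet:::with_seed
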