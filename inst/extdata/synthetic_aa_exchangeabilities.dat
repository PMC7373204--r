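# Synthetic amino-acid exchangeability matrix in PAML .dat layout.
# Randomly generated example for read_paml_matrix(); NOT an empirical model.
1.683
0.3397 1.1494
0.9187 0.5134 0.0808
0.4794 0.3606 1.1203 0.6226
0.6648 0.4817 0.8014 0.7979 0.0783
3.8459 1.8523 1.243 0.4472 1.9932 0.7199
0.8482 0.2486 4.3311 1.0494 6.7402 5.646 1.0599
1.9066 5.6161 0.5892 1.181 0.7751 1.3948 1.2001 3.2046
1.8103 0.4099 1.7811 0.4383 0.3143 2.1771 0.2999 1.359 0.4345
4.1294 2.0376 0.6686 2.2241 1.5319 0.3104 0.8137 0.3943 1.5674 0.5248
0.7934 0.2904 0.3825 1.1433 0.3682 0.8681 1.1821 0.8197 0.7474 0.1765 0.7613
0.1653 3.1669 0.3667 1.1598 1.6812 1.0055 3.846 0.4287 1.558 0.3764 8.3686 1.9891
0.7094 2.1928 0.3149 4.5218 0.3149 0.2108 0.9463 2.3378 0.989 0.4675 3.2407 11.1836 0.1411
4.3649 0.622 2.6676 0.1613 0.7706 0.3833 0.6124 0.3405 1.4469 3.3746 0.6103 0.7963 0.329 2.707
1.7539 0.2092 4.3977 0.3106 0.3492 0.2295 0.3032 0.7061 1.7037 0.4912 0.8196 0.7547 3.225 9.8624 0.3434
6.7275 8.43 1.2604 2.4521 0.1757 1.5982 0.5803 0.8475 1.737 2.8104 0.9549 13.9951 1.8022 0.8168 1.5551 0.9046
0.3351 1.6541 2.5837 1.4664 1.45 1.1702 2.3348 0.2771 3.1844 0.4029 1.3979 2.1724 1.2676 0.2102 1.0246 1.3974 2.6896
1.6493 1.7805 3.1352 0.4929 0.5387 0.9917 1.4034 4.0772 0.4209 0.4173 2.1691 0.6691 0.8064 1.8317 0.5409 0.4846 0.7734 0.6757
0.5032 2.4009 0.6181 1.0707 1.1469 0.1559 1.4138 4.489 0.9864 0.4606 3.7105 1.2976 2.7567 1.2406 1.8467 4.246 1.9311 1.4553 0.5093

0.05668 0.04120 0.05527 0.03652 0.07591 0.04054 0.05443 0.06082 0.02156 0.05465 0.04389 0.04546 0.07838 0.04079 0.03620 0.07614 0.03491 0.04452 0.04245 0.05968
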