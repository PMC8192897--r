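school,effect,estimate,stderr,significant
School1,Density [ArcA],-3.681,0.412,TRUE
School1,Reciprocity [ReciprocityA],3.103,0.247,TRUE
School1,Popularity spread [AinSA],-0.74,0.17,TRUE
School1,Activity spread [AoutSA],0.768,0.153,TRUE
School1,Path closure [ATA-T],1.048,0.08,TRUE
School1,Multiple 2-paths [A2PA-T],-0.14,0.032,TRUE
School1,Gender-Sender,-0.761,0.19,TRUE
School1,Gender-Receiver,-0.496,0.183,TRUE
School1,Gender-Interaction,1.35,0.234,TRUE
School1,PS-Sender,0.061,0.281,FALSE
School1,PS-Receiver,0.292,0.316,FALSE
School1,Knowledge-Sender,0.109,0.049,TRUE
School1,Knowledge-Receiver,-0.006,0.057,FALSE
School1,Knowledge-Difference,-0.025,0.042,FALSE
School1,Norms-Sender,-0.061,0.044,FALSE
School1,Norms-Receiver,0.05,0.053,FALSE
School1,Norms-Difference,-0.104,0.043,TRUE
School1,Talking-Sender,0.012,0.035,FALSE
School1,Talking-Receiver,-0.058,0.046,FALSE
School1,Talking-Difference,-0.069,0.028,TRUE
School1,PS Talking-Sender,0.031,0.086,FALSE
School1,PS Talking-Receiver,0.026,0.087,FALSE
School1,Indegree [In2StarAX],0.01,0.037,FALSE
School1,Outdegree [Out2StarAX],-0.028,0.032,FALSE
School1,Cross-level arc [TXAXarc],0.415,0.048,TRUE
School1,Cross-level 3-paths [L3XAX],-0.024,0.006,TRUE
School2,Density [ArcA],-3.211,0.536,TRUE
School2,Reciprocity [ReciprocityA],1.866,0.238,TRUE
School2,Popularity spread [AinSA],-0.8,0.249,TRUE
School2,Activity spread [AoutSA],1.057,0.208,TRUE
School2,Path closure [ATA-T],0.975,0.08,TRUE
School2,Multiple 2-paths [A2PA-T],-0.203,0.034,TRUE
School2,Gender-Sender,-1.806,0.418,TRUE
School2,Gender-Receiver,-1.409,0.344,TRUE
School2,Gender-Interaction,3.516,0.515,TRUE
School2,PS-Sender,-0.927,0.364,TRUE
School2,PS-Receiver,0.272,0.364,FALSE
School2,Knowledge-Sender,0.03,0.06,FALSE
School2,Knowledge-Receiver,-0.04,0.064,FALSE
School2,Knowledge-Difference,-0.032,0.055,FALSE
School2,Norms-Sender,0.033,0.049,FALSE
School2,Norms-Receiver,0.049,0.053,FALSE
School2,Norms-Difference,-0.065,0.044,FALSE
School2,Talking-Sender,-0.098,0.046,TRUE
School2,Talking-Receiver,0.223,0.049,TRUE
School2,Talking-Difference,-0.035,0.034,FALSE
School2,PS Talking-Sender,0.635,0.225,TRUE
School2,PS Talking-Receiver,-0.367,0.176,TRUE
School2,Indegree [In2StarAX],0.129,0.063,TRUE
School2,Outdegree [Out2StarAX],-0.204,0.07,TRUE
School2,Cross-level arc [TXAXarc],0.627,0.117,TRUE
School2,Cross-level 3-paths [L3XAX],-0.052,0.018,TRUE
School3,Density [ArcA],-3.855,0.382,TRUE
School3,Reciprocity [ReciprocityA],2.705,0.207,TRUE
School3,Popularity spread [AinSA],-0.368,0.14,TRUE
School3,Activity spread [AoutSA],0.789,0.182,TRUE
School3,Path closure [ATA-T],1.249,0.061,TRUE
School3,Multiple 2-paths [A2PA-T],-0.145,0.023,TRUE
School3,Gender-Sender,-0.73,0.141,TRUE
School3,Gender-Receiver,-0.12,0.103,FALSE
School3,Gender-Interaction,0.883,0.12,TRUE
School3,PS-Sender,1.304,0.628,TRUE
School3,PS-Receiver,-0.205,0.393,FALSE
School3,Knowledge-Sender,-0.099,0.046,TRUE
School3,Knowledge-Receiver,0.041,0.039,FALSE
School3,Knowledge-Difference,-0.091,0.025,TRUE
School3,Norms-Sender,0.035,0.046,FALSE
School3,Norms-Receiver,-0.001,0.039,FALSE
School3,Norms-Difference,-0.088,0.029,TRUE
School3,Talking-Sender,0.049,0.037,FALSE
School3,Talking-Receiver,-0.02,0.029,FALSE
School3,Talking-Difference,-0.073,0.02,TRUE
School3,PS Talking-Sender,-0.424,0.173,TRUE
School3,PS Talking-Receiver,0.134,0.113,FALSE
School3,Indegree [In2StarAX],-0.009,0.068,FALSE
School3,Outdegree [Out2StarAX],0.013,0.096,FALSE
School3,Cross-level arc [TXAXarc],0.793,0.243,TRUE
School3,Cross-level 3-paths [L3XAX],-0.117,0.076,FALSE
School5,Density [ArcA],-3.973,0.413,TRUE
School5,Reciprocity [ReciprocityA],2.894,0.243,TRUE
School5,Popularity spread [AinSA],-0.47,0.179,TRUE
School5,Activity spread [AoutSA],0.659,0.182,TRUE
School5,Path closure [ATA-T],1.173,0.08,TRUE
School5,Multiple 2-paths [A2PA-T],-0.104,0.031,TRUE
School5,Gender-Sender,-0.69,0.171,TRUE
School5,Gender-Receiver,-0.419,0.167,TRUE
School5,Gender-Interaction,0.942,0.191,TRUE
School5,PS-Sender,-0.605,0.315,FALSE
School5,PS-Receiver,0.824,0.267,TRUE
School5,Knowledge-Sender,0.039,0.051,FALSE
School5,Knowledge-Receiver,0.004,0.054,FALSE
School5,Knowledge-Difference,-0.111,0.038,TRUE
School5,Norms-Sender,-0.079,0.049,FALSE
School5,Norms-Receiver,0.107,0.05,TRUE
School5,Norms-Difference,-0.061,0.04,FALSE
School5,Talking-Sender,-0.134,0.045,TRUE
School5,Talking-Receiver,0.151,0.047,TRUE
School5,Talking-Difference,-0.071,0.028,TRUE
School5,PS Talking-Sender,0.118,0.103,FALSE
School5,PS Talking-Receiver,-0.046,0.074,FALSE
School5,Indegree [In2StarAX],-0.077,0.037,TRUE
School5,Outdegree [Out2StarAX],0.045,0.038,FALSE
School5,Cross-level arc [TXAXarc],0.294,0.041,TRUE
School5,Cross-level 3-paths [L3XAX],-0.02,0.005,TRUE
School6,Density [ArcA],-2.476,0.493,TRUE
School6,Reciprocity [ReciprocityA],1.926,0.24,TRUE
School6,Popularity spread [AinSA],-0.596,0.186,TRUE
School6,Activity spread [AoutSA],0.364,0.216,FALSE
School6,Path closure [ATA-T],1.292,0.079,TRUE
School6,Multiple 2-paths [A2PA-T],-0.144,0.03,TRUE
School6,Gender-Sender,-0.474,0.166,TRUE
School6,Gender-Receiver,-0.539,0.17,TRUE
School6,Gender-Interaction,1.144,0.181,TRUE
School6,PS-Sender,0.158,0.36,FALSE
School6,PS-Receiver,0.093,0.283,FALSE
School6,Knowledge-Sender,0.001,0.051,FALSE
School6,Knowledge-Receiver,-0.007,0.044,FALSE
School6,Knowledge-Difference,-0.128,0.028,TRUE
School6,Norms-Sender,-0.052,0.051,FALSE
School6,Norms-Receiver,-0.017,0.043,FALSE
School6,Norms-Difference,-0.008,0.04,FALSE
School6,Talking-Sender,-0.025,0.041,FALSE
School6,Talking-Receiver,0.072,0.036,TRUE
School6,Talking-Difference,-0.07,0.028,TRUE
School6,PS Talking-Sender,-0.086,0.16,FALSE
School6,PS Talking-Receiver,0.136,0.105,FALSE
School6,Indegree [In2StarAX],-0.017,0.042,FALSE
School6,Outdegree [Out2StarAX],-0.086,0.05,FALSE
School6,Cross-level arc [TXAXarc],0.535,0.107,TRUE
School6,Cross-level 3-paths [L3XAX],-0.049,0.022,TRUE
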