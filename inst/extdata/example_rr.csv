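rr_ms
793
804
794
795
809
804
800
795
793
794
804
797
788
787
1150
778
773
755
757
755
762
770
782
787
794
791
803
815
810
803
805
814
832
842
853
861
853
837
823
822
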